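#' Build and validate a pipeline run configuration
#'
#' One flat configuration with per-stage sections; unknown keys are
#' errors. Stage parameter defaults encode the analysis rules: two-fold
#' change at FDR < 0.05, fold enrichment needing at least 5 genes at
#' p < 0.001, 1 kb promoters, conservation in at least 5 species
#' including a distal one, and 10,000 resampled gene sets for the Z-test.
#'
#' @param mode `"synthetic"` (inputs generated from `sim`) or `"user"`
#'   (inputs read from `paths`).
#' @param seed global integer seed; per-stage seeds derive from it via
#'   [derive_seed()].
#' @param out_dir output directory for the report bundle.
#' @param sim list of [sim_config()] overrides (synthetic mode).
#' @param paths named list of input paths (user mode): `expr` (named list
#'   per contrast), `genome`, `annotation`, `alignments_dir`,
#'   `categories`.
#' @param de list: `fc_threshold_log2` (1), `q_threshold` (0.05).
#' @param enrich list: `min_genes` (5), `p_threshold` (0.001), `n_perm`
#'   (1000).
#' @param motifs list: `promoter_length` (1000), `min_species` (5),
#'   `require_distal` (TRUE).
#' @param ztest list: `n_samples` (10000), `statistic`
#'   ("genes_with_site").
#' @return validated list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "user"), seed = 1,
                       out_dir = tempfile("regenprofiler_run_"),
                       sim = list(), paths = list(), de = list(),
                       enrich = list(), motifs = list(), ztest = list()) {
  mode <- match.arg(mode)
  defaults <- list(
    de = list(fc_threshold_log2 = 1, q_threshold = 0.05),
    enrich = list(min_genes = 5, p_threshold = 0.001, n_perm = 1000),
    motifs = list(promoter_length = 1000, min_species = 5,
                  require_distal = TRUE),
    ztest = list(n_samples = 10000, statistic = "genes_with_site"))
  merge_section <- function(name, user) {
    bad <- setdiff(names(user), names(defaults[[name]]))
    if (length(bad))
      stop("unknown ", name, " config keys: ", paste(bad, collapse = ", "))
    modifyList(defaults[[name]], user)
  }
  if (mode == "synthetic") {
    bad <- setdiff(names(sim), names(formals(sim_config)))
    if (length(bad))
      stop("unknown sim config keys: ", paste(bad, collapse = ", "))
  }
  cfg <- structure(list(
    mode = mode, seed = as.integer(seed), out_dir = out_dir,
    sim = sim, paths = paths,
    de = merge_section("de", de),
    enrich = merge_section("enrich", enrich),
    motifs = merge_section("motifs", motifs),
    ztest = merge_section("ztest", ztest)
  ), class = "run_config")
  if (mode == "user") {
    need <- c("expr", "genome", "annotation", "alignments_dir",
              "categories")
    miss <- setdiff(need, names(paths))
    if (length(miss))
      stop("user mode requires paths: ", paste(miss, collapse = ", "))
    flat <- c(unlist(paths$expr), paths$genome, paths$annotation,
              paths$alignments_dir, paths$categories)
    gone <- flat[!file.exists(flat)]
    if (length(gone))
      stop("input path(s) not found: ", paste(gone, collapse = ", "))
  }
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the [run_config()] sections.
#' @return validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("mode", "seed", "out_dir", "sim", "paths", "de", "enrich",
             "motifs", "ztest")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, y)
}

#' Run the full regeneration-profiling pipeline
#'
#' simulate (or load) -> dye-swap normalize + call the three contrasts ->
#' assign temporal classes and the early-regeneration signature ->
#' fold/running-sum enrichment -> promoter extraction, motif scan and
#' conservation filter -> resampling Z-tests for the up/down sets and the
#' planted/assigned Class III set -> TSV report bundle plus a manifest
#' with parameters, seed and output digests. Rerunning the same
#' configuration reproduces every output byte-identically.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with every stage result and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...)
    message(sprintf("[%s] %s", stage, sprintf(...)))

  # --- stage: inputs -------------------------------------------------
  if (config$mode == "synthetic") {
    log_stage("simulate", "generating synthetic inputs (seed %d)",
              config$seed)
    sim_args <- config$sim
    sim_args$seed <- sim_args$seed %||% derive_seed(config$seed, "sim")
    scfg <- do.call(sim_config, sim_args)
    gen <- generate_expression(scfg)
    expr <- gen$expr
    pro <- generate_promoters(scfg, gen$truth)
    aln <- generate_alignments(scfg, pro$truth, pro$promoters)
    truth <- aln$truth
    genome <- pro$genome
    annotation <- pro$annotation
    alignments <- aln$alignments
    categories <- generate_categories(scfg, truth)
    dye_swap <- scfg$dye_swap_pattern
    motif_models <- scfg$motif_models
    species_panel <- scfg$species_panel
    promoter_length <- scfg$promoter_length
    write_expression(do.call(cbind, lapply(names(expr), function(ct) {
      m <- expr[[ct]]; colnames(m) <- paste(ct, colnames(m), sep = "_"); m
    })), file.path(config$out_dir, "expression_raw.tsv"))
    write_tsv(truth$genes, file.path(config$out_dir, "ground_truth.tsv"))
  } else {
    log_stage("load", "reading user inputs")
    expr <- lapply(config$paths$expr, read_expression)
    if (!all(names(expr) %in% contrast_names()))
      stop("expr contrasts must be named among: ",
           paste(contrast_names(), collapse = ", "))
    genome <- Biostrings::readDNAStringSet(config$paths$genome)
    annotation <- read_bed(config$paths$annotation)
    alignments <- read_alignments(config$paths$alignments_dir)
    categories <- read_categories(config$paths$categories)
    truth <- NULL
    dye_swap <- rep(FALSE, ncol(expr[[1]]))
    motif_models <- list(motif_model("AP1", consensus = "TGASTCA"),
                         motif_model("Ebox", consensus = "CACGTG"))
    species_panel <- default_species_panel()
    promoter_length <- config$motifs$promoter_length
  }

  if (!all(contrast_names() %in% names(expr)))
    stop("pipeline requires all three contrasts: ",
         paste(contrast_names(), collapse = ", "))

  # --- stage: differential expression -------------------------------
  log_stage("de", "calling contrasts at |log2FC| >= %g, q < %g",
            config$de$fc_threshold_log2, config$de$q_threshold)
  calls <- lapply(expr, function(m)
    call_contrast(normalize_replicates(m, dye_swap),
                  fc_threshold_log2 = config$de$fc_threshold_log2,
                  q_threshold = config$de$q_threshold))
  for (ct in names(calls))
    write_tsv(calls[[ct]],
              file.path(config$out_dir, paste0("calls_", ct, ".tsv")))

  # --- stage: temporal classes --------------------------------------
  log_stage("classes", "assigning temporal classes")
  assignments <- assign_classes(calls$C0_C24, calls$C24_C72)
  signature <- early_signature(calls$C0_C24, calls$NC0_NC24)
  composition <- composition_report(assignments,
    extra_contrasts = calls["NC0_NC24"])
  write_tsv(assignments, file.path(config$out_dir, "classes.tsv"))
  write_tsv(composition$totals,
            file.path(config$out_dir, "composition_totals.tsv"))
  write_tsv(composition$classes,
            file.path(config$out_dir, "composition_classes.tsv"))
  writeLines(signature$up_only,
             file.path(config$out_dir, "signature_up_only.txt"))
  writeLines(signature$down_only,
             file.path(config$out_dir, "signature_down_only.txt"))

  # --- stage: enrichment --------------------------------------------
  log_stage("enrich", "fold enrichment and running-sum scores")
  up_c1 <- calls$C0_C24$gene[calls$C0_C24$call == "up"]
  fold <- if (length(up_c1) > 0)
    fold_enrichment(up_c1, categories,
                    min_genes = config$enrich$min_genes,
                    p_threshold = config$enrich$p_threshold)
  else empty_fold()
  write_tsv(fold, file.path(config$out_dir, "fold_enrichment.tsv"))
  ranked <- rank_genes(
    setNames(calls$C0_C24$log2FC, calls$C0_C24$gene),
    setNames(calls$C24_C72$log2FC, calls$C24_C72$gene))
  gsea_rows <- lapply(names(categories$categories), function(nm) {
    members <- categories$categories[[nm]]
    if (length(members) >= length(categories$universe)) return(NULL)
    r <- gsea_es(ranked, members, n_perm = config$enrich$n_perm,
                 seed = derive_seed(config$seed, paste0("gsea_", nm)))
    data.frame(category = nm, ES = r$ES, p_perm = r$p_perm,
               zero_cross_index = r$zero_cross_index,
               n_members = length(members), stringsAsFactors = FALSE)
  })
  gsea <- do.call(rbind, gsea_rows)
  write_tsv(gsea, file.path(config$out_dir, "gsea.tsv"))

  # --- stage: motifs -------------------------------------------------
  log_stage("motifs", "extracting %d bp promoters and scanning %d motifs",
            promoter_length, length(motif_models))
  promoters <- extract_promoters(genome, annotation,
                                 length = promoter_length)
  site_tabs <- list()
  for (m in motif_models) {
    st <- scan_motif(promoters, m)
    st <- conservation_filter(st, m, alignments,
                              species_panel = species_panel,
                              min_species = config$motifs$min_species,
                              require_distal = config$motifs$require_distal)
    st$motif <- if (nrow(st)) m$name else character(0)
    site_tabs[[m$name]] <- st
  }
  sites <- do.call(rbind, site_tabs)
  rownames(sites) <- NULL
  write_tsv(sites, file.path(config$out_dir, "conserved_sites.tsv"))

  # --- stage: Z-tests ------------------------------------------------
  log_stage("ztest", "resampling Z-tests (%d samples)",
            config$ztest$n_samples)
  universe <- names(promoters)  # genes with a usable promoter
  gene_sets <- list(
    up_C0_C24 = intersect(up_c1, universe),
    down_C0_C24 = intersect(
      calls$C0_C24$gene[calls$C0_C24$call == "down"], universe),
    up_C24_C72 = intersect(
      calls$C24_C72$gene[calls$C24_C72$call == "up"], universe),
    down_C24_C72 = intersect(
      calls$C24_C72$gene[calls$C24_C72$call == "down"], universe),
    class_III = intersect(
      assignments$gene[assignments$class == "III"], universe))
  ztests <- list()
  for (m in motif_models) {
    msites <- site_tabs[[m$name]]
    for (set_name in names(gene_sets)) {
      gs <- gene_sets[[set_name]]
      if (length(gs) == 0 || length(gs) >= length(universe)) next
      zt <- ztest_enrichment(
        gs, universe, msites, statistic = config$ztest$statistic,
        n_samples = config$ztest$n_samples,
        seed = derive_seed(config$seed,
                           paste0("ztest_", m$name, "_", set_name)))
      row <- as.data.frame(zt)
      row <- cbind(data.frame(motif = m$name, gene_set = set_name,
                              set_size = length(gs),
                              stringsAsFactors = FALSE), row)
      ztests[[length(ztests) + 1L]] <- row
    }
  }
  ztab <- if (length(ztests)) do.call(rbind, ztests) else NULL
  write_tsv(ztab, file.path(config$out_dir, "ztest.tsv"))

  # --- manifest ------------------------------------------------------
  outputs <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  digests <- tools::md5sum(file.path(config$out_dir, outputs))
  manifest <- list(
    mode = config$mode, seed = config$seed,
    parameters = config[c("sim", "de", "enrich", "motifs", "ztest")],
    outputs = setNames(as.list(unname(digests)), outputs))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(calls = calls, assignments = assignments,
                 signature = signature, composition = composition,
                 fold_enrichment = fold, gsea = gsea, sites = sites,
                 ztests = ztab, truth = truth, promoters = promoters,
                 manifest = manifest, out_dir = config$out_dir))
}

empty_fold <- function() {
  data.frame(category = character(), k = integer(), n = integer(),
             K = integer(), N = integer(), fold = numeric(),
             p = numeric(), stringsAsFactors = FALSE)
}
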
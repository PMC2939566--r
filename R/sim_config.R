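#' Default 12-species Drosophila panel
#'
#' The reference species (D. melanogaster) first, then eleven informants
#' in published phylogenetic order with an increasing distance rank. The
#' `distal` flag marks D. pseudoobscura and everything more distant --
#' the species that can satisfy the conservation filter's requirement
#' for at least one sufficiently diverged informant.
#'
#' @return data.frame with columns `species`, `rank` (0 for the
#'   reference), `distal`.
#' @export
default_species_panel <- function() {
  species <- c("Dmel", "Dsim", "Dsec", "Dyak", "Dere", "Dana",
               "Dpse", "Dper", "Dwil", "Dmoj", "Dvir", "Dgri")
  data.frame(
    species = species,
    rank = seq_along(species) - 1L,
    distal = species %in% c("Dpse", "Dper", "Dwil", "Dmoj", "Dvir", "Dgri"),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic regeneration data generator
#'
#' The generator plants a known temporal class structure (Class I-IV plus
#' flat genes) into replicate log2-ratio tables for the three contrasts
#' NC0_NC24, C0_C24 and C24_C72, plants motif instances into uniform
#' random promoters, and degrades them across a species panel so that the
#' whole downstream pipeline can be validated against ground truth.
#'
#' Defaults describe the emulated study conditions: four hybridizations
#' per contrast in dye-swapped pairs, a planted effect of 2 log2 units
#' with 0.3 log2 units of replicate noise, 1 kb promoters, and a
#' 12-species panel.
#'
#' @param n_genes number of genes.
#' @param replicates_per_contrast replicate arrays per contrast (default 4).
#' @param dye_swap_pattern logical per replicate; `TRUE` replicates are
#'   stored sign-flipped and must be re-flipped by [normalize_replicates()].
#' @param class_proportions named fractions for classes I-IV; the
#'   remainder of the genome is flat. Must sum to <= 1.
#' @param effect_size_log2 planted |log2 fold change| for regulated genes.
#' @param noise_sd_log2 Gaussian replicate noise SD (log2 units).
#' @param nc_shared_fraction probability that a gene regulated in C0_C24
#'   is also regulated (same direction) in the uncut NC0_NC24 contrast.
#' @param nc_only_fraction probability that a flat gene is regulated only
#'   in NC0_NC24.
#' @param class3_up_down_fraction fraction of Class III genes with the
#'   up-then-down pattern (the remainder are down-then-up).
#' @param species_panel data.frame as [default_species_panel()];
#'   reference species must be first (rank 0).
#' @param per_branch_retention probability that a planted site is retained
#'   intact in the nearest informant; decays with distance rank as
#'   `retention^(1 + retention_rank_decay * (rank - 1))`.
#' @param retention_rank_decay decay exponent per distance rank.
#' @param align_background_mutation per-column substitution probability in
#'   informants outside retained sites.
#' @param align_gap_rate expected insertion events per promoter column.
#' @param motif_models list of [motif_model()] objects to plant and scan.
#' @param planted_motif_rate_target probability that a target-class gene
#'   receives a planted instance of each motif.
#' @param planted_motif_rate_background same for all other genes.
#' @param motif_target_classes class labels whose genes are motif targets
#'   (default Class III, the transient injury-response genes).
#' @param promoter_length promoter length in bases (default 1000).
#' @param n_random_categories random gene categories emitted alongside the
#'   per-class ones by [generate_categories()].
#' @param seed integer seed; all generator stages derive their streams
#'   from it via [derive_seed()].
#' @return An object of class `sim_config` (validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 100, seed = 1)
#' cfg$promoter_length
sim_config <- function(n_genes = 2000,
                       replicates_per_contrast = 4,
                       dye_swap_pattern = c(FALSE, TRUE, FALSE, TRUE),
                       class_proportions = c(I = 0.05, II = 0.02,
                                             III = 0.01, IV = 0.01),
                       effect_size_log2 = 2,
                       noise_sd_log2 = 0.3,
                       nc_shared_fraction = 0.5,
                       nc_only_fraction = 0.01,
                       class3_up_down_fraction = 0.9,
                       species_panel = default_species_panel(),
                       per_branch_retention = 0.9,
                       retention_rank_decay = 0.15,
                       align_background_mutation = 0.2,
                       align_gap_rate = 0.01,
                       motif_models = list(
                         motif_model("AP1", consensus = "TGASTCA"),
                         motif_model("Ebox", consensus = "CACGTG")),
                       planted_motif_rate_target = 0.8,
                       planted_motif_rate_background = 0.05,
                       motif_target_classes = "III",
                       promoter_length = 1000,
                       n_random_categories = 20,
                       seed = 1) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_genes) || cfg$n_genes < 1)
    stop("configuration error: n_genes must be a positive count")
  if (!is.numeric(cfg$noise_sd_log2) || cfg$noise_sd_log2 <= 0)
    stop("configuration error: noise_sd_log2 must be positive")
  if (cfg$effect_size_log2 < 0)
    stop("configuration error: effect_size_log2 must be >= 0")
  if (length(cfg$dye_swap_pattern) != cfg$replicates_per_contrast)
    stop("configuration error: dye_swap_pattern length must equal ",
         "replicates_per_contrast")
  cp <- cfg$class_proportions
  if (is.null(names(cp)) || !all(names(cp) %in% c("I", "II", "III", "IV")))
    stop("configuration error: class_proportions must be named with I-IV")
  probs <- c(cp, cfg$nc_shared_fraction, cfg$nc_only_fraction,
             cfg$class3_up_down_fraction, cfg$per_branch_retention,
             cfg$align_background_mutation,
             cfg$planted_motif_rate_target,
             cfg$planted_motif_rate_background)
  if (any(probs < 0 | probs > 1))
    stop("configuration error: all probabilities must lie in [0, 1]")
  if (sum(cp) > 1)
    stop("configuration error: class_proportions must sum to <= 1")
  sp <- cfg$species_panel
  if (!is.data.frame(sp) || nrow(sp) < 1 ||
      !all(c("species", "rank", "distal") %in% names(sp)))
    stop("configuration error: species_panel needs columns ",
         "species/rank/distal")
  if (sp$rank[1] != 0)
    stop("configuration error: species_panel must list the reference ",
         "species first (rank 0)")
  for (m in cfg$motif_models) {
    if (!inherits(m, "motif_model"))
      stop("configuration error: motif_models must be motif_model objects")
    if (m$width > cfg$promoter_length)
      stop("configuration error: motif '", m$name,
           "' is longer than the promoter")
  }
  if (cfg$promoter_length < 1)
    stop("configuration error: promoter_length must be positive")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d genes x %d replicates/contrast (dye swaps: %s)\n",
    x$n_genes, x$replicates_per_contrast,
    paste(which(x$dye_swap_pattern), collapse = ",")))
  cat(sprintf("  effect %.2f log2, noise %.2f log2; classes: %s\n",
              x$effect_size_log2, x$noise_sd_log2,
              paste(sprintf("%s=%.3f", names(x$class_proportions),
                            x$class_proportions), collapse = " ")))
  cat(sprintf("  promoters %d bp, %d motifs, %d species, seed %d\n",
              x$promoter_length, length(x$motif_models),
              nrow(x$species_panel), x$seed))
  invisible(x)
}

# Contrast vocabulary used throughout the package.
contrast_names <- function() c("NC0_NC24", "C0_C24", "C24_C72")

# Per-informant retention probability of a planted site.
species_retention_probs <- function(cfg) {
  inf <- cfg$species_panel[-1, , drop = FALSE]
  p <- cfg$per_branch_retention ^
    (1 + cfg$retention_rank_decay * (inf$rank - 1))
  setNames(p, inf$species)
}
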
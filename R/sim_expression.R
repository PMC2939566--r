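#' Generate replicate log2-ratio tables with planted temporal classes
#'
#' Each gene is assigned a temporal class (I-IV or flat) and direction
#' pattern over the two cut-disc contrasts, plus an uncut-disc direction.
#' Replicate values are the planted mean (+/- `effect_size_log2`, 0 for
#' flat genes) plus Gaussian noise. Replicates whose `dye_swap_pattern`
#' flag is `TRUE` are stored sign-flipped, as raw two-colour log ratios
#' would be; [normalize_replicates()] undoes the flip.
#'
#' @param config a [sim_config()].
#' @return A list with `expr` (named list of gene x replicate matrices,
#'   one per contrast NC0_NC24 / C0_C24 / C24_C72) and `truth`
#'   (class `regen_truth`), whose `$genes` data.frame records per-gene
#'   class, directions (`dir_nc`, `dir_c1`, `dir_c2` in -1/0/1) and the
#'   `motif_target` flag.
#' @export
#' @examples
#' sim <- generate_expression(sim_config(n_genes = 50, seed = 1))
#' head(sim$truth$genes)
generate_expression <- function(config) {
  validate_sim_config(config)
  n <- as.integer(config$n_genes)
  genes <- sprintf("g%05d", seq_len(n))

  with_seed(derive_seed(config$seed, "expression"), {
    cls <- rep("none", n)
    counts <- floor(config$class_proportions * n)
    perm <- sample.int(n)
    pos <- 0L
    for (lab in names(counts)) {
      k <- counts[[lab]]
      if (k > 0) cls[perm[pos + seq_len(k)]] <- lab
      pos <- pos + k
    }

    sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
    dir_c1 <- integer(n); dir_c2 <- integer(n)
    i1 <- cls == "I";  dir_c1[i1] <- sgn(sum(i1))
    i2 <- cls == "II"; dir_c2[i2] <- sgn(sum(i2))
    i3 <- cls == "III"
    if (any(i3)) {
      updown <- runif(sum(i3)) < config$class3_up_down_fraction
      dir_c1[i3] <- ifelse(updown, 1, -1)
      dir_c2[i3] <- -dir_c1[i3]
    }
    i4 <- cls == "IV"
    if (any(i4)) { s <- sgn(sum(i4)); dir_c1[i4] <- s; dir_c2[i4] <- s }

    dir_nc <- integer(n)
    reg1 <- dir_c1 != 0
    dir_nc[reg1] <- dir_c1[reg1] *
      (runif(sum(reg1)) < config$nc_shared_fraction)
    flat <- cls == "none" & dir_c2 == 0
    nco <- flat & runif(n) < config$nc_only_fraction
    dir_nc[nco] <- sgn(sum(nco))

    if (config$effect_size_log2 == 0) {
      # a zero effect plants nothing: the ground truth is all flat
      cls[] <- "none"
      dir_nc[] <- 0L; dir_c1[] <- 0L; dir_c2[] <- 0L
    }

    dirs <- list(NC0_NC24 = dir_nc, C0_C24 = dir_c1, C24_C72 = dir_c2)
    R <- config$replicates_per_contrast
    flip <- ifelse(config$dye_swap_pattern, -1, 1)
    expr <- lapply(dirs, function(d) {
      m <- matrix(d * config$effect_size_log2, n, R) +
        matrix(rnorm(n * R, sd = config$noise_sd_log2), n, R)
      m <- sweep(m, 2, flip, "*")
      dimnames(m) <- list(genes, paste0("rep", seq_len(R)))
      m
    })

    truth <- structure(list(
      genes = data.frame(
        gene = genes, class = cls,
        dir_nc = dir_nc, dir_c1 = dir_c1, dir_c2 = dir_c2,
        motif_target = cls %in% config$motif_target_classes,
        stringsAsFactors = FALSE)
    ), class = "regen_truth")
    list(expr = expr, truth = truth)
  })
}

#' Generate a ground-truthed category map
#'
#' Emits one category per planted temporal class (members = that class's
#' genes) plus `n_random_categories` random categories of sizes 10-50,
#' over the full gene universe. Used to exercise the enrichment stages
#' with known positives.
#'
#' @param config a [sim_config()].
#' @param truth `regen_truth` from [generate_expression()].
#' @return A [category_map()].
#' @export
generate_categories <- function(config, truth) {
  g <- truth$genes
  cats <- list()
  for (lab in c("I", "II", "III", "IV")) {
    members <- g$gene[g$class == lab]
    if (length(members) > 0) cats[[paste0("class_", lab)]] <- members
  }
  with_seed(derive_seed(config$seed, "categories"), {
    for (i in seq_len(config$n_random_categories)) {
      size <- sample(10:min(50, nrow(g)), 1)
      cats[[sprintf("random_%02d", i)]] <- sort(sample(g$gene, size))
    }
  })
  category_map(cats, universe = g$gene)
}
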
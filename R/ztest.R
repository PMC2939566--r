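#' Conserved-site burden of a gene set
#'
#' Counts only sites with `passes_conservation = TRUE`: the number of
#' genes in the set carrying at least one passing site, and the total
#' number of passing sites over the set.
#'
#' @param gene_set character vector of gene ids.
#' @param sites data.frame from [conservation_filter()].
#' @return list with `genes_with_site` and `total_sites`.
#' @export
site_burden <- function(gene_set, sites) {
  passing <- sites[isTRUE_vec(sites$passes_conservation) &
                     sites$gene %in% gene_set, , drop = FALSE]
  list(genes_with_site = length(unique(passing$gene)),
       total_sites = nrow(passing))
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Resampling Z-test for conserved-site enrichment
#'
#' Compares the conserved-site burden of a gene set against `n_samples`
#' equal-size random gene sets drawn without replacement from the
#' universe. Reports the null mean and SD, Z = (observed - mean)/sd, the
#' one-sided upper-tail normal p, and the empirical tail fraction
#' (add-one smoothed). With `exhaustive = TRUE` (small universes) every
#' subset is enumerated instead of sampled and the null moments are
#' exact population values.
#'
#' @param gene_set character vector; proper subset of `universe`.
#' @param universe character vector of all genes with a usable promoter.
#' @param sites data.frame from [conservation_filter()].
#' @param statistic `"genes_with_site"` or `"total_sites"`.
#' @param n_samples resample count (default 10000).
#' @param seed integer seed.
#' @param exhaustive enumerate all subsets (requires `choose(N, m)` <=
#'   `max_exhaustive`).
#' @param max_exhaustive guard on exhaustive enumeration size.
#' @return Object of class `regen_ztest`: list with `statistic`,
#'   `observed`, `mean`, `sd`, `Z`, `p_normal`, `p_empirical`,
#'   `n_samples`, `samples`, `degenerate`, `seed`.
#' @export
ztest_enrichment <- function(gene_set, universe, sites,
                             statistic = c("genes_with_site",
                                           "total_sites"),
                             n_samples = 10000, seed = 1,
                             exhaustive = FALSE, max_exhaustive = 2e5) {
  statistic <- match.arg(statistic)
  universe <- unique(as.character(universe))
  gene_set <- unique(as.character(gene_set))
  if (!all(gene_set %in% universe))
    stop("gene_set must be a subset of the universe")
  m <- length(gene_set); N <- length(universe)
  if (m == 0 || m >= N)
    stop("gene_set must be a nonempty proper subset of the universe")

  passing <- sites[isTRUE_vec(sites$passes_conservation), , drop = FALSE]
  counts <- setNames(integer(N), universe)
  if (nrow(passing)) {
    tab <- table(passing$gene[passing$gene %in% universe])
    counts[names(tab)] <- as.integer(tab)
  }
  stat_of <- if (statistic == "genes_with_site") {
    function(cnt) sum(cnt > 0L)
  } else {
    function(cnt) sum(cnt)
  }
  observed <- stat_of(counts[gene_set])

  if (exhaustive) {
    if (choose(N, m) > max_exhaustive)
      stop("universe too large for exhaustive enumeration")
    subsets <- combn(N, m)
    samples <- apply(subsets, 2, function(ix) stat_of(counts[ix]))
    mu <- mean(samples)
    sdev <- sqrt(mean((samples - mu)^2))  # population SD over all subsets
    n_used <- ncol(subsets)
  } else {
    samples <- with_seed(seed, vapply(seq_len(n_samples), function(b)
      stat_of(counts[sample.int(N, m)]), numeric(1)))
    mu <- mean(samples)
    sdev <- sd(samples)
    n_used <- n_samples
  }

  degenerate <- !is.finite(sdev) || sdev == 0
  if (degenerate) {
    z <- NA_real_
    p_norm <- if (observed <= mu) 1 else 0
  } else {
    z <- (observed - mu) / sdev
    p_norm <- pnorm(z, lower.tail = FALSE)
  }
  p_emp <- (1 + sum(samples >= observed)) / (n_used + 1)

  structure(list(
    statistic = statistic, observed = observed, mean = mu, sd = sdev,
    Z = z, p_normal = p_norm, p_empirical = p_emp,
    n_samples = n_used, samples = samples, degenerate = degenerate,
    seed = if (exhaustive) NA_integer_ else seed,
    set_size = m, universe_size = N
  ), class = "regen_ztest")
}

#' @export
print.regen_ztest <- function(x, ...) {
  cat(sprintf(
    "resampling Z-test (%s): observed %d vs null %.3f +/- %.3f over %d draws\n",
    x$statistic, x$observed, x$mean, x$sd, x$n_samples))
  if (x$degenerate) {
    cat(sprintf("  degenerate null (sd = 0); p = %g\n", x$p_normal))
  } else {
    cat(sprintf("  Z = %.3f, normal p = %.3g, empirical p = %.3g\n",
                x$Z, x$p_normal, x$p_empirical))
  }
  invisible(x)
}

#' @export
as.data.frame.regen_ztest <- function(x, ...) {
  data.frame(statistic = x$statistic, observed = x$observed,
             null_mean = x$mean, null_sd = x$sd, Z = x$Z,
             p_normal = x$p_normal, p_empirical = x$p_empirical,
             n_samples = x$n_samples, seed = x$seed,
             stringsAsFactors = FALSE)
}
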
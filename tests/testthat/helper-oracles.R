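# Independent brute-force oracles and small fixture builders. These are
# deliberately naive re-implementations kept separate from the package
# code paths they validate.

# Benjamini-Hochberg step-up, computed literally from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running_min <- Inf
  for (i in m:1) {
    val <- p[ord[i]] * m / i
    running_min <- min(running_min, val)
    q[ord[i]] <- min(running_min, 1)
  }
  q
}

# Hypergeometric upper tail P(X >= k) as an exact sum of choose() ratios.
oracle_hyper_tail <- function(k, K, N, n) {
  if (k <= 0) return(1)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_revcomp <- function(x) {
  paste(rev(unname(c(A = "T", C = "G", G = "C", T = "A")[
    strsplit(x, "")[[1]]])), collapse = "")
}

# Character-by-character sliding-window IUPAC scan of one sequence.
# Returns (offset, strand, match) rows with the scanner's palindromic
# collapse: identical (offset, spanned plus-strand sequence) across
# strands is reported once as "+".
oracle_scan <- function(seq, consensus) {
  w <- nchar(consensus)
  L <- nchar(seq)
  cons <- strsplit(consensus, "")[[1]]
  rc_cons <- strsplit(
    paste(rev(unname(c(A = "T", C = "G", G = "C", T = "A",
                       R = "Y", Y = "R", S = "S", W = "W", K = "M",
                       M = "K", B = "V", V = "B", D = "H", H = "D",
                       N = "N")[cons])), collapse = ""), "")[[1]]
  rows <- list()
  if (L >= w) {
    for (o in 0:(L - w)) {
      win <- strsplit(substr(seq, o + 1, o + w), "")[[1]]
      plus <- all(mapply(function(b, c) b %in% iupac_sets[[c]], win, cons))
      minus <- all(mapply(function(b, c) b %in% iupac_sets[[c]], win,
                          rc_cons))
      span <- paste(win, collapse = "")
      if (plus)
        rows[[length(rows) + 1L]] <- data.frame(
          offset = o, strand = "+", match = span,
          stringsAsFactors = FALSE)
      if (minus && !(plus))  # collapse: + record subsumes the - one
        rows[[length(rows) + 1L]] <- data.frame(
          offset = o, strand = "-", match = span,
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(offset = integer(), strand = character(),
                      match = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Brute-force unweighted running-sum walk in exact integer steps
# (member +n_miss, miss -n_hit, scaled back at the end); ES is the
# signed extremum of largest magnitude, positive tail on exact ties.
oracle_es <- function(hits) {
  n_hit <- sum(hits)
  n_miss <- length(hits) - n_hit
  acc <- 0
  rs_scaled <- numeric(length(hits))
  for (i in seq_along(hits)) {
    acc <- acc + if (hits[i]) n_miss else -n_hit
    rs_scaled[i] <- acc
  }
  rs <- rs_scaled / (n_hit * n_miss)
  mx <- max(rs); mn <- min(rs)
  list(running_sum = rs, ES = if (mx >= -mn) mx else mn)
}

# Convolve a count pmf (index 0-based) with one Bernoulli(p).
convolve_bernoulli <- function(pmf, p) {
  out <- numeric(length(pmf) + 1)
  out[seq_along(pmf)] <- pmf * (1 - p)
  out[seq_along(pmf) + 1] <- out[seq_along(pmf) + 1] + pmf * p
  out
}

# Random DNA string.
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# Minimal call_contrast-shaped data.frame.
make_calls <- function(genes, calls) {
  data.frame(gene = genes, log2FC = 0, p = 1, q = 1, call = calls,
             stringsAsFactors = FALSE)
}

# Build the three-contrast call fixture shaped like the published count
# table: per-pattern gene counts for (c1, c2) plus a separate uncut
# contrast with the given up/down totals, in a universe of `n_universe`.
table1_fixture <- function(n_universe = 2500) {
  patterns <- list(
    list(n = 496, c1 = "up",   c2 = "flat"),  # Class I up
    list(n = 538, c1 = "down", c2 = "flat"),  # Class I down
    list(n = 51,  c1 = "flat", c2 = "up"),    # Class II up
    list(n = 81,  c1 = "flat", c2 = "down"),  # Class II down
    list(n = 48,  c1 = "up",   c2 = "down"),  # Class III up->down
    list(n = 2,   c1 = "down", c2 = "up"),    # Class III down->up
    list(n = 63,  c1 = "up",   c2 = "up"),    # Class IV up
    list(n = 36,  c1 = "down", c2 = "down"))  # Class IV down
  n_pat <- sum(vapply(patterns, `[[`, 0, "n"))
  genes <- sprintf("g%04d", seq_len(n_universe))
  c1 <- rep("flat", n_universe)
  c2 <- rep("flat", n_universe)
  pos <- 0
  for (p in patterns) {
    idx <- pos + seq_len(p$n)
    c1[idx] <- p$c1
    c2[idx] <- p$c2
    pos <- pos + p$n
  }
  # uncut contrast: 407 up, 356 down, anywhere in the universe
  nc <- rep("flat", n_universe)
  nc[1:407] <- "up"
  nc[408:763] <- "down"
  list(c1 = make_calls(genes, c1), c2 = make_calls(genes, c2),
       nc = make_calls(genes, nc), n_regulated = n_pat)
}
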
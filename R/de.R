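#' Dye-swap correction and median centring of replicate log ratios
#'
#' Simplified stand-in for full two-colour array normalization: replicates
#' flagged as dye swaps are sign-flipped back to the common orientation,
#' then every replicate column is median-centred to zero.
#'
#' @param raw numeric gene x replicate matrix of log2 ratios (rownames =
#'   gene ids).
#' @param dye_swap_pattern logical per replicate column; `TRUE` columns
#'   are sign-flipped.
#' @return Corrected matrix of the same shape.
#' @export
#' @examples
#' m <- matrix(c(1, -1), 1, 2, dimnames = list("g1", c("r1", "r2")))
#' normalize_replicates(m, c(FALSE, TRUE))
normalize_replicates <- function(raw, dye_swap_pattern) {
  raw <- as.matrix(raw)
  if (ncol(raw) < 2)
    stop("insufficient replication: need >= 2 replicates, got ", ncol(raw))
  if (length(dye_swap_pattern) != ncol(raw))
    stop("dye_swap_pattern length must equal the number of replicates")
  corrected <- sweep(raw, 2, ifelse(dye_swap_pattern, -1, 1), "*")
  sweep(corrected, 2, apply(corrected, 2, median), "-")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differential expression for one contrast
#'
#' Per-gene mean log2 fold change with a one-sample t test of the
#' replicate log ratios against zero; Benjamini-Hochberg q over all genes
#' in the contrast; a gene is called `up` iff `log2FC >= fc_threshold_log2`
#' and `q < q_threshold`, `down` iff `log2FC <= -fc_threshold_log2` and
#' `q < q_threshold`, else `flat`. The defaults encode the two-fold /
#' FDR < 0.05 rule. Zero-variance genes get p = 0 when the mean is
#' nonzero and p = 1 otherwise (deterministic degenerate rule).
#'
#' @param corrected gene x replicate matrix from [normalize_replicates()].
#' @param fc_threshold_log2 log2 fold-change threshold (default 1, i.e.
#'   two-fold).
#' @param q_threshold FDR threshold (default 0.05).
#' @return data.frame with columns `gene`, `log2FC`, `p`, `q`, `call`.
#' @export
#' @examples
#' m <- matrix(rnorm(40), 10, 4,
#'             dimnames = list(paste0("g", 1:10), paste0("r", 1:4)))
#' head(call_contrast(m))
call_contrast <- function(corrected, fc_threshold_log2 = 1,
                          q_threshold = 0.05) {
  corrected <- as.matrix(corrected)
  n_rep <- ncol(corrected)
  if (n_rep < 2)
    stop("insufficient replication: need >= 2 replicates, got ", n_rep)
  means <- rowMeans(corrected)
  sds <- apply(corrected, 1, sd)
  p <- numeric(nrow(corrected))
  zero_var <- sds == 0
  p[zero_var] <- ifelse(means[zero_var] != 0, 0, 1)
  if (any(!zero_var)) {
    tt <- means[!zero_var] / (sds[!zero_var] / sqrt(n_rep))
    p[!zero_var] <- 2 * pt(-abs(tt), df = n_rep - 1)
  }
  q <- bh_fdr(p)
  call <- rep("flat", length(p))
  call[means >= fc_threshold_log2 & q < q_threshold] <- "up"
  call[means <= -fc_threshold_log2 & q < q_threshold] <- "down"
  data.frame(gene = rownames(corrected) %||% as.character(seq_along(p)),
             log2FC = unname(means), p = p, q = q, call = call,
             stringsAsFactors = FALSE)
}

#' Relative expression by the delta-CT method
#'
#' CT of the target normalized by subtracting the geometric average of
#' three reference-gene CTs; relative expression is `2^(-deltaCT)`.
#'
#' @param target_ct target gene cycle threshold (scalar).
#' @param control_cts numeric vector of three reference-gene CTs.
#' @return list with `delta_ct` and `relative_expression`.
#' @export
#' @examples
#' qpcr_delta_ct(19, c(20, 20, 20))  # one cycle earlier -> 2-fold
qpcr_delta_ct <- function(target_ct, control_cts) {
  if (length(control_cts) != 3)
    stop("exactly three control CT values are required")
  cts <- c(target_ct, control_cts)
  if (!is.numeric(cts) || any(!is.finite(cts)) || any(cts <= 0))
    stop("all CT values must be positive and finite")
  geo <- exp(mean(log(control_cts)))
  dct <- target_ct - geo
  list(delta_ct = dct, relative_expression = 2^(-dct))
}
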
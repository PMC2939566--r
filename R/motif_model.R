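#' Motif models: IUPAC consensus or position weight matrix
#'
#' A motif model is either a degenerate IUPAC consensus string (matched
#' exactly, every position must fall in the allowed letter set) or a
#' position weight matrix of per-base scores (a hit requires
#' score >= `score_threshold` x maximal achievable score). The defaults
#' shipped with the package are the AP1 site consensus `TGASTCA`
#' (Jun/Fos dimer downstream of JNK signalling) and the palindromic
#' E-box `CACGTG` bound by bHLH factors such as E(spl). The published AP1
#' matrix is not redistributed here; users holding it can supply it as a
#' PWM via `pwm =`.
#'
#' @param name motif name.
#' @param consensus IUPAC consensus string (mutually exclusive with `pwm`).
#' @param pwm numeric matrix, 4 rows named A,C,G,T, one column per motif
#'   position. Raw count matrices (JASPAR-style) are converted to log2
#'   odds against a uniform background with a 0.25 pseudocount; matrices
#'   with negative entries are taken as ready-made score matrices.
#' @param score_threshold PWM mode only: fraction of the maximal score in
#'   `[0, 1]` required for a hit (default 0.8).
#' @return An object of class `motif_model` with fields `name`, `mode`
#'   (`"iupac"` or `"pwm"`), `consensus` or `pwm`, `width`,
#'   `score_threshold`.
#' @export
#' @examples
#' motif_model("AP1", consensus = "TGASTCA")
#' motif_model("Ebox", consensus = "CACGTG")
motif_model <- function(name, consensus = NULL, pwm = NULL,
                        score_threshold = 0.8) {
  if (is.null(consensus) == is.null(pwm))
    stop("supply exactly one of `consensus` or `pwm`")
  if (!is.null(consensus)) {
    consensus <- toupper(consensus)
    if (!iupac_valid(consensus))
      stop("invalid IUPAC letters in consensus: ", consensus)
    width <- nchar(consensus)
    if (width < 4L) stop("motif width must be >= 4 (got ", width, ")")
    out <- list(name = name, mode = "iupac", consensus = consensus,
                width = width)
  } else {
    pwm <- as.matrix(pwm)
    if (nrow(pwm) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
    if (is.null(rownames(pwm))) rownames(pwm) <- c("A", "C", "G", "T")
    pwm <- pwm[c("A", "C", "G", "T"), , drop = FALSE]
    if (!all(is.finite(pwm))) stop("PWM entries must be finite")
    if (all(pwm >= 0)) {  # count/frequency matrix -> log2 odds
      freq <- sweep(pwm + 0.25, 2, colSums(pwm + 0.25), "/")
      pwm <- log2(freq / 0.25)
    }
    width <- ncol(pwm)
    if (width < 4L) stop("motif width must be >= 4 (got ", width, ")")
    if (!is.numeric(score_threshold) || score_threshold < 0 ||
        score_threshold > 1)
      stop("score_threshold must be in [0, 1]")
    out <- list(name = name, mode = "pwm", pwm = pwm, width = width,
                score_threshold = score_threshold)
  }
  structure(out, class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  if (x$mode == "iupac") {
    cat(sprintf("motif_model '%s': IUPAC consensus %s (width %d)\n",
                x$name, x$consensus, x$width))
  } else {
    cat(sprintf(
      "motif_model '%s': PWM, width %d, threshold %.2f x max score\n",
      x$name, x$width, x$score_threshold))
  }
  invisible(x)
}

#' Read a PWM from whitespace-delimited text
#'
#' Accepts a simple 4-row numeric matrix (rows A, C, G, T, optionally
#' labelled) or a JASPAR-style block `A [ 1 2 ... ]`. Counts are
#' converted to log-odds by [motif_model()].
#'
#' @param path file path.
#' @param name motif name (default: file base name).
#' @param score_threshold passed to [motif_model()].
#' @return A `motif_model`.
#' @export
read_pwm <- function(path, name = NULL, score_threshold = 0.8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), ">")]
  lines <- gsub("[][]", " ", lines)
  rows <- lapply(lines, function(l) strsplit(trimws(l), "[[:space:]]+")[[1]])
  lab <- vapply(rows, function(r) toupper(r[1]) %in% c("A", "C", "G", "T"),
                logical(1))
  mat <- if (all(lab)) {
    m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
    rownames(m) <- vapply(rows, function(r) toupper(r[1]), character(1))
    m
  } else {
    do.call(rbind, lapply(rows, as.numeric))
  }
  motif_model(name %||% sub("\\.[^.]*$", "", basename(path)), pwm = mat,
              score_threshold = score_threshold)
}

# Allowed plus-strand bases at motif position j for the site oriented on
# `strand` of the promoter. For strand "-", promoter position offset+j-1
# carries the complement of motif position width-j+1.
allowed_bases_at <- function(model, j, strand = "+") {
  tab <- iupac_table()
  if (model$mode == "iupac") {
    letters <- strsplit(model$consensus, "")[[1]]
    if (strand == "+") return(tab[[letters[j]]])
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    unname(comp[tab[[letters[model$width - j + 1]]]])
  } else {
    best <- rownames(model$pwm)[model$pwm[, if (strand == "+") j else
      model$width - j + 1] == max(model$pwm[, if (strand == "+") j else
        model$width - j + 1])]
    if (strand == "+") return(best)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    unname(comp[best])
  }
}

# PWM score of every window of an integer-coded sequence (1=A..4=T).
pwm_window_scores <- function(codes, pwm) {
  w <- ncol(pwm)
  n <- length(codes) - w + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(w)) s <- s + pwm[cbind(codes[j:(j + n - 1L)], j)]
  s
}

# Does a short plain string contain a PWM hit on either strand?
pwm_hit_anywhere <- function(seq, model) {
  if (nchar(seq) < model$width) return(FALSE)
  thr <- model$score_threshold * sum(apply(model$pwm, 2, max))
  code <- function(s) match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  for (s in c(seq, revcomp_chr(seq))) {
    cd <- code(s)
    if (anyNA(cd)) next
    if (length(pwm_window_scores(cd, model$pwm)) &&
        any(pwm_window_scores(cd, model$pwm) >= thr)) return(TRUE)
  }
  FALSE
}

# Exact-width plus-strand match of a string against the model.
motif_full_match_plus <- function(seq, model) {
  if (nchar(seq) != model$width) return(FALSE)
  if (model$mode == "iupac")
    return(grepl(paste0("^", iupac_regex(model$consensus), "$"), seq))
  cd <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  if (anyNA(cd)) return(FALSE)
  thr <- model$score_threshold * sum(apply(model$pwm, 2, max))
  pwm_window_scores(cd, model$pwm)[1] >= thr
}

# Dispatch: any-strand hit on a short window, for either motif mode.
motif_hit_anywhere <- function(seq, model) {
  if (model$mode == "iupac") iupac_hit_anywhere(seq, model$consensus)
  else pwm_hit_anywhere(seq, model)
}
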
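# Shared helpers: seeded evaluation, seed derivation, IUPAC tables.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded package functions
#' do not disturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a stage seed from a global seed
#'
#' Deterministic string hash of the stage name folded into the global seed,
#' kept below 2^31 so it is a valid R integer seed. One global knob gives
#' independent, reproducible streams per pipeline stage.
#'
#' @param seed global integer seed.
#' @param stage stage name (character scalar).
#' @return integer seed.
#' @export
#' @examples
#' derive_seed(1, "expression")
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 2654435 + h) %% 2147483647)
}

# IUPAC nucleotide codes -> allowed bases
iupac_table <- function() {
  list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
  )
}

iupac_valid <- function(consensus) {
  all(strsplit(toupper(consensus), "")[[1]] %in% names(iupac_table()))
}

# Reverse complement of a plain character string (ACGT + IUPAC codes).
revcomp_chr <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(comp, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

# IUPAC consensus -> regular expression character classes.
iupac_regex <- function(consensus) {
  tab <- iupac_table()
  letters <- strsplit(toupper(consensus), "")[[1]]
  paste(vapply(letters, function(l) {
    b <- tab[[l]]
    if (length(b) == 1L) b else paste0("[", paste(b, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# Does `seq` (plain string) contain >=1 occurrence of the consensus on
# either strand? Used on short conservation windows.
iupac_hit_anywhere <- function(seq, consensus) {
  if (nchar(seq) < nchar(consensus)) return(FALSE)
  rx <- iupac_regex(consensus)
  grepl(rx, seq) || grepl(rx, revcomp_chr(seq))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
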
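# Plain-text I/O: TSV tables, FASTA, BED-like annotation, alignment dirs.

#' Write/read a replicate expression table
#'
#' TSV with a `gene` column followed by one column per replicate.
#'
#' @param expr gene x replicate matrix.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_expression
#' @param path input path.
#' @return matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a BED-like 6-column annotation table
#'
#' Columns chrom, start, end, gene, score, strand; 0-based half-open, no
#' header (standard BED convention).
#'
#' @param annotation data.frame with those columns.
#' @param path output path.
#' @export
write_bed <- function(annotation, path) {
  write.table(annotation[, c("chrom", "start", "end", "gene", "score",
                             "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' @rdname write_bed
#' @return data.frame chrom/start/end/gene/score/strand.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:6] <- c("chrom", "start", "end", "gene", "score", "strand")
  df
}

#' Write per-gene promoter alignments as aligned multi-FASTA files
#'
#' One file `<gene>.fa` per promoter under `dir`, reference species
#' first, all rows equal width.
#'
#' @param alignments per-gene named character vectors of aligned rows.
#' @param dir output directory (created if needed).
#' @export
write_alignments <- function(alignments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (gene in names(alignments)) {
    aln <- alignments[[gene]]
    x <- Biostrings::BStringSet(aln)
    names(x) <- names(aln)
    Biostrings::writeXStringSet(x, file.path(dir, paste0(gene, ".fa")))
  }
  invisible(dir)
}

#' @rdname write_alignments
#' @return named list of per-gene aligned rows.
#' @export
read_alignments <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.fa$", full.names = TRUE))
  out <- lapply(files, function(f) {
    x <- Biostrings::readBStringSet(f)
    setNames(as.character(x), names(x))
  })
  names(out) <- sub("\\.fa$", "", basename(files))
  out
}

write_tsv <- function(df, path) {
  if (is.null(df)) df <- data.frame()
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
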
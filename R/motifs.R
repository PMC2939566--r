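#' Extract promoters upstream of annotated TSSs
#'
#' For a plus-strand gene with TSS at 0-based coordinate t, the promoter
#' is bases `[t - length, t)` of the contig; for a minus-strand gene it
#' is the reverse complement of `[t + 1, t + 1 + length)`. Promoters are
#' truncated at contig edges with a warning; a TSS outside its contig
#' produces a per-gene error record and the run continues.
#'
#' @param genome named `DNAStringSet` (or path to a FASTA file).
#' @param annotation BED-like data.frame with columns `chrom`, `start`,
#'   `end`, `gene`, `score`, `strand`; 0-based half-open, the TSS base at
#'   `start`.
#' @param length promoter length in bases (default 1000).
#' @return Named `DNAStringSet` of promoters, with attribute `errors`
#'   (data.frame `gene`, `reason`) for skipped genes.
#' @export
extract_promoters <- function(genome, annotation, length = 1000) {
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  need <- c("chrom", "start", "gene", "strand")
  if (!all(need %in% names(annotation)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  out <- vector("list", nrow(annotation))
  errors <- list()
  truncated <- character(0)
  for (i in seq_len(nrow(annotation))) {
    gene <- annotation$gene[i]
    chrom <- annotation$chrom[i]
    if (!chrom %in% names(genome)) {
      errors[[length(errors) + 1L]] <-
        data.frame(gene = gene, reason = paste0("unknown contig ", chrom))
      next
    }
    chr <- genome[[chrom]]
    clen <- Biostrings::nchar(chr)
    t0 <- annotation$start[i]
    if (t0 < 0 || t0 >= clen) {
      errors[[length(errors) + 1L]] <-
        data.frame(gene = gene, reason = "TSS outside contig")
      next
    }
    if (annotation$strand[i] == "+") {
      from <- max(0L, t0 - length); to <- t0          # 0-based half-open
      if (from > t0 - length) truncated <- c(truncated, gene)
      seq <- if (to > from) Biostrings::subseq(chr, from + 1L, to)
             else Biostrings::DNAString("")
    } else {
      from <- t0 + 1L; to <- min(clen, t0 + 1L + length)
      if (to < t0 + 1L + length) truncated <- c(truncated, gene)
      seq <- if (to > from) {
        Biostrings::reverseComplement(Biostrings::subseq(chr, from + 1L, to))
      } else Biostrings::DNAString("")
    }
    out[[i]] <- setNames(list(seq), gene)
  }
  if (length(truncated))
    warning("promoters truncated at contig edge for: ",
            paste(head(truncated, 10), collapse = ", "),
            if (length(truncated) > 10) " ...")
  out <- out[!vapply(out, is.null, logical(1))]
  res <- Biostrings::DNAStringSet(lapply(out, `[[`, 1))
  names(res) <- vapply(out, function(x) names(x), character(1))
  attr(res, "errors") <- if (length(errors)) do.call(rbind, errors)
    else data.frame(gene = character(), reason = character())
  res
}

#' Scan promoters for motif occurrences on both strands
#'
#' IUPAC mode matches the degenerate consensus exactly at every offset of
#' both strands (via `Biostrings::vmatchPattern` with the subject held
#' literal); PWM mode reports windows whose log-odds score reaches
#' `score_threshold` x the maximal score. Coordinates are 0-based offsets
#' on the promoter's plus strand. Sites found on both strands over the
#' identical span with the identical spanned sequence (palindromes such
#' as CACGTG, and pseudo-palindromic consensi) are collapsed to a single
#' `+` record.
#'
#' @param promoters named `DNAStringSet` (or FASTA path).
#' @param model a [motif_model()].
#' @param collapse_palindromes collapse double-stranded duplicates
#'   (default `TRUE`).
#' @return data.frame `gene`, `offset`, `strand`, `match` (spanned
#'   promoter plus-strand sequence), `score`.
#' @export
#' @examples
#' pr <- Biostrings::DNAStringSet(c(g1 = "AACACGTGTT"))
#' scan_motif(pr, motif_model("Ebox", consensus = "CACGTG"))
scan_motif <- function(promoters, model, collapse_palindromes = TRUE) {
  if (is.character(promoters))
    promoters <- Biostrings::readDNAStringSet(promoters)
  stopifnot(inherits(model, "motif_model"))
  w <- model$width
  lens <- Biostrings::width(promoters)
  if (any(lens < w)) {
    warning("skipping promoters shorter than the motif: ",
            paste(head(names(promoters)[lens < w], 10), collapse = ", "))
    promoters <- promoters[lens >= w]
  }
  if (length(promoters) == 0)
    return(empty_sites())

  rows <- list()
  if (model$mode == "iupac") {
    pat <- Biostrings::DNAString(model$consensus)
    rcp <- Biostrings::reverseComplement(pat)
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else rcp
      hits <- Biostrings::vmatchPattern(p, promoters, fixed = "subject")
      for (g in seq_along(promoters)) {
        ir <- hits[[g]]
        if (length(ir) == 0) next
        off <- IRanges::start(ir) - 1L
        spans <- as.character(Biostrings::extractAt(promoters[[g]], ir))
        rows[[length(rows) + 1L]] <- data.frame(
          gene = names(promoters)[g], offset = off, strand = strand,
          match = spans, score = 1, stringsAsFactors = FALSE)
      }
    }
  } else {
    thr <- model$score_threshold * sum(apply(model$pwm, 2, max))
    rc_pwm <- model$pwm[c("T", "G", "C", "A"), rev(seq_len(w)), drop = FALSE]
    rownames(rc_pwm) <- c("A", "C", "G", "T")
    for (g in seq_along(promoters)) {
      s <- as.character(promoters[[g]])
      codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
      for (strand in c("+", "-")) {
        mat <- if (strand == "+") model$pwm else rc_pwm
        sc <- pwm_window_scores(codes, mat)
        hit <- which(!is.na(sc) & sc >= thr)
        if (length(hit) == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          gene = names(promoters)[g], offset = hit - 1L, strand = strand,
          match = substring(s, hit, hit + w - 1L), score = sc[hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty_sites())
  sites <- do.call(rbind, rows)
  if (collapse_palindromes) {
    key <- paste(sites$gene, sites$offset, sites$match)
    dup <- duplicated(key)
    keep_plus <- tapply(sites$strand == "+", key, any)[key]
    sites$strand[keep_plus] <- "+"
    sites <- sites[!dup, , drop = FALSE]
  }
  sites <- sites[order(sites$gene, sites$offset, sites$strand), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  sites
}

empty_sites <- function() {
  data.frame(gene = character(), offset = integer(), strand = character(),
             match = character(), score = numeric(),
             stringsAsFactors = FALSE)
}

#' Phylogenetic conservation filter for motif sites
#'
#' For every site, the alignment columns spanning the reference site are
#' taken (optionally widened by `slack` columns), gaps are dropped per
#' informant species, and the motif model is re-tested against the
#' resulting subsequence on both strands. A site passes when it is
#' conserved in at least `min_species` informants and (if
#' `require_distal`) at least one of them carries the distal flag
#' (D. pseudoobscura or more distant).
#'
#' @param sites data.frame from [scan_motif()].
#' @param model the [motif_model()] the sites were scanned with.
#' @param alignments per-gene named character vectors of aligned rows
#'   (reference first), as from [generate_alignments()].
#' @param species_panel data.frame as [default_species_panel()].
#' @param min_species minimum conserved informants (default 5).
#' @param require_distal require a distal-flagged informant (default
#'   `TRUE`). Methods-style rule; set `require_pseudoobscura` to demand
#'   D. pseudoobscura itself.
#' @param require_pseudoobscura species name that must itself be among
#'   the conserved informants (`NULL` to disable; e.g. `"Dpse"`).
#' @param slack widen the aligned window by this many columns on each
#'   side (default 0).
#' @return `sites` with added columns `conserved_in` (comma-separated
#'   species), `n_conserved`, `passes_conservation`; attribute `errors`
#'   for genes without an alignment.
#' @export
conservation_filter <- function(sites, model, alignments,
                                species_panel = default_species_panel(),
                                min_species = 5, require_distal = TRUE,
                                require_pseudoobscura = NULL, slack = 0) {
  stopifnot(inherits(model, "motif_model"))
  distal_species <- species_panel$species[species_panel$distal]
  conserved_in <- character(nrow(sites))
  n_conserved <- integer(nrow(sites))
  passes <- logical(nrow(sites))
  errors <- list()
  ref_maps <- new.env(parent = emptyenv())  # cache per-gene column maps

  for (i in seq_len(nrow(sites))) {
    gene <- sites$gene[i]
    aln <- alignments[[gene]]
    if (is.null(aln)) {
      errors[[length(errors) + 1L]] <-
        data.frame(gene = gene, reason = "missing alignment")
      next
    }
    if (!exists(gene, envir = ref_maps)) {
      refchars <- strsplit(aln[[1]], "")[[1]]
      assign(gene, list(cols = which(refchars != "-"),
                        rows = lapply(aln, function(s) strsplit(s, "")[[1]]),
                        width = nchar(aln[[1]])),
             envir = ref_maps)
    }
    mp <- get(gene, envir = ref_maps)
    o <- sites$offset[i]
    if (o + model$width > length(mp$cols)) next  # site beyond reference
    span <- max(1L, mp$cols[o + 1L] - slack):
            min(mp$width, mp$cols[o + model$width] + slack)
    hit_species <- character(0)
    for (s in names(aln)[-1]) {
      sub <- mp$rows[[s]][span]
      sub <- paste(sub[sub != "-"], collapse = "")
      if (motif_hit_anywhere(sub, model))
        hit_species <- c(hit_species, s)
    }
    conserved_in[i] <- paste(hit_species, collapse = ",")
    n_conserved[i] <- length(hit_species)
    ok <- length(hit_species) >= min_species &&
      (!require_distal || any(hit_species %in% distal_species))
    if (!is.null(require_pseudoobscura))
      ok <- ok && require_pseudoobscura %in% hit_species
    passes[i] <- ok
  }
  sites$conserved_in <- conserved_in
  sites$n_conserved <- n_conserved
  sites$passes_conservation <- passes
  attr(sites, "errors") <- if (length(errors)) do.call(rbind, errors)
    else data.frame(gene = character(), reason = character())
  sites
}
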
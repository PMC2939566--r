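#' Generate promoters with planted motif instances and a matching genome
#'
#' Builds one uniform-random promoter per gene, plants concrete instances
#' of each configured motif (target-class genes at
#' `planted_motif_rate_target`, all others at
#' `planted_motif_rate_background`), and embeds every promoter in a small
#' synthetic contig so that [extract_promoters()] applied to the emitted
#' genome and TSS annotation recovers exactly the emitted promoter
#' sequences. Genes alternate between plus and minus strand to exercise
#' the strand convention.
#'
#' @param config a [sim_config()].
#' @param truth `regen_truth` from [generate_expression()].
#' @return A list: `promoters` (named `DNAStringSet`), `genome`
#'   (`DNAStringSet`, one contig per gene), `annotation` (BED-like
#'   data.frame: chrom, start, end, gene, score, strand; 0-based
#'   half-open, the TSS base at `start`), and `truth` augmented with
#'   `$planted_sites` (gene, motif, offset, strand, instance).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 10, promoter_length = 200, seed = 1)
#' sim <- generate_expression(cfg)
#' pro <- generate_promoters(cfg, sim$truth)
#' names(pro)
generate_promoters <- function(config, truth) {
  validate_sim_config(config)
  g <- truth$genes
  n <- nrow(g)
  L <- as.integer(config$promoter_length)
  bases <- c("A", "C", "G", "T")
  pad_len <- 50L
  tab <- iupac_table()

  with_seed(derive_seed(config$seed, "promoters"), {
    prom <- character(n)
    planted <- list()
    for (i in seq_len(n)) {
      chars <- sample(bases, L, replace = TRUE)
      occupied <- logical(L)
      rate <- if (g$motif_target[i]) config$planted_motif_rate_target
              else config$planted_motif_rate_background
      for (m in config$motif_models) {
        if (runif(1) >= rate) next
        w <- m$width
        # draw a non-overlapping slot; give up quietly after 10 tries
        off <- NA_integer_
        for (try in 1:10) {
          cand <- sample.int(L - w + 1L, 1L) - 1L
          if (!any(occupied[(cand + 1L):(cand + w)])) { off <- cand; break }
        }
        if (is.na(off)) next
        strand <- sample(c("+", "-"), 1L)
        instance <- if (m$mode == "iupac") {
          paste(vapply(strsplit(m$consensus, "")[[1]],
                       function(l) sample(tab[[l]], 1L), character(1)),
                collapse = "")
        } else {
          paste(rownames(m$pwm)[apply(m$pwm, 2, which.max)], collapse = "")
        }
        written <- if (strand == "+") instance else revcomp_chr(instance)
        # strand-ambiguous writes (palindromes, pseudo-palindromic
        # consensi like TGASTCA) are recorded as "+", matching the
        # scanner's collapsing rule
        if (strand == "-" && motif_full_match_plus(written, m))
          strand <- "+"
        chars[(off + 1L):(off + w)] <- strsplit(written, "")[[1]]
        occupied[(off + 1L):(off + w)] <- TRUE
        planted[[length(planted) + 1L]] <- data.frame(
          gene = g$gene[i], motif = m$name, offset = off, strand = strand,
          instance = instance, stringsAsFactors = FALSE)
      }
      prom[i] <- paste(chars, collapse = "")
    }

    strand <- ifelse(seq_len(n) %% 2L == 1L, "+", "-")
    pads <- vapply(seq_len(n), function(i)
      paste(sample(bases, pad_len, replace = TRUE), collapse = ""),
      character(1))
    contig <- ifelse(strand == "+", paste0(prom, pads),
                     paste0(pads, revcomp_chr(prom)))
    tss <- ifelse(strand == "+", L, pad_len - 1L)

    genome <- Biostrings::DNAStringSet(contig)
    names(genome) <- paste0("scaf_", g$gene)
    promoters <- Biostrings::DNAStringSet(prom)
    names(promoters) <- g$gene
    annotation <- data.frame(
      chrom = names(genome), start = as.integer(tss),
      end = as.integer(tss) + 1L, gene = g$gene, score = 0L,
      strand = strand, stringsAsFactors = FALSE)

    truth$planted_sites <- if (length(planted)) {
      do.call(rbind, planted)
    } else {
      data.frame(gene = character(), motif = character(),
                 offset = integer(), strand = character(),
                 instance = character(), stringsAsFactors = FALSE)
    }
    list(promoters = promoters, genome = genome, annotation = annotation,
         truth = truth)
  })
}
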
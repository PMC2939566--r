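#' Generate multi-species promoter alignments with known site retention
#'
#' Emulates a genome-browser style multiple alignment of the promoter
#' across the configured species panel. For every informant species each
#' planted site is either retained intact (probability
#' `per_branch_retention`, decaying with the species' distance rank) or
#' deliberately degraded by substituting every site position with a base
#' outside the motif's allowed set, so a degraded site can never match on
#' either strand. Non-site columns mutate at `align_background_mutation`;
#' insertion events (gap in all other rows) occur at `align_gap_rate` per
#' column, never inside a planted site.
#'
#' @param config a [sim_config()].
#' @param truth `regen_truth` carrying `$planted_sites` (from
#'   [generate_promoters()]).
#' @param promoters named `DNAStringSet` of reference promoters.
#' @return A list: `alignments` (per-gene named character vector of
#'   aligned rows, reference species first, equal widths) and `truth`
#'   augmented with `$retention` (gene, motif, offset, species, retained),
#'   one row per planted site x informant.
#' @export
generate_alignments <- function(config, truth, promoters) {
  validate_sim_config(config)
  panel <- config$species_panel
  if (nrow(panel) < 1) stop("configuration error: empty species_panel")
  informants <- panel$species[-1]
  ret_p <- species_retention_probs(config)
  bases <- c("A", "C", "G", "T")
  models <- setNames(config$motif_models,
                     vapply(config$motif_models, `[[`, "", "name"))
  sites <- truth$planted_sites

  with_seed(derive_seed(config$seed, "alignments"), {
    alignments <- vector("list", length(promoters))
    names(alignments) <- names(promoters)
    retention <- list()

    for (gene in names(promoters)) {
      ref <- strsplit(as.character(promoters[[gene]]), "")[[1]]
      L <- length(ref)
      gsites <- sites[sites$gene == gene, , drop = FALSE]
      site_mask <- logical(L)
      if (nrow(gsites)) {
        for (k in seq_len(nrow(gsites))) {
          w <- models[[gsites$motif[k]]]$width
          site_mask[(gsites$offset[k] + 1L):(gsites$offset[k] + w)] <- TRUE
        }
      }

      rows <- matrix("", nrow = nrow(panel), ncol = L,
                     dimnames = list(panel$species, NULL))
      rows[1, ] <- ref
      for (s in informants) {
        chars <- ref
        keep_mask <- logical(L)  # retained site columns: no bg mutation
        if (nrow(gsites)) {
          for (k in seq_len(nrow(gsites))) {
            m <- models[[gsites$motif[k]]]
            w <- m$width
            span <- (gsites$offset[k] + 1L):(gsites$offset[k] + w)
            retained <- runif(1) < ret_p[[s]]
            if (retained) {
              keep_mask[span] <- TRUE
            } else {
              # break the site at every position where the union of
              # allowed bases (both orientations) leaves room
              for (j in seq_len(w)) {
                allowed <- union(allowed_bases_at(m, j, gsites$strand[k]),
                                 allowed_bases_at(m, j,
                                   if (gsites$strand[k] == "+") "-" else "+"))
                forb <- setdiff(bases, allowed)
                if (length(forb))
                  chars[span[j]] <- forb[sample.int(length(forb), 1L)]
              }
              keep_mask[span] <- TRUE  # degraded deliberately, skip bg
            }
            retention[[length(retention) + 1L]] <- data.frame(
              gene = gene, motif = gsites$motif[k],
              offset = gsites$offset[k], species = s, retained = retained,
              stringsAsFactors = FALSE)
          }
        }
        mut <- runif(L) < config$align_background_mutation & !keep_mask
        if (any(mut)) {
          idx <- which(mut)
          shift <- sample.int(3L, length(idx), replace = TRUE)
          chars[idx] <- bases[(match(chars[idx], bases) - 1L + shift) %% 4L + 1L]
        }
        rows[s, ] <- chars
      }

      # insertion events: a new column with a base in one informant and
      # gaps everywhere else, at boundaries outside planted sites
      n_ins <- rpois(1, config$align_gap_rate * L)
      if (n_ins > 0 && length(informants) > 0) {
        interior <- logical(L + 1L)  # boundary b = before ref position b+1
        if (nrow(gsites)) {
          for (k in seq_len(nrow(gsites))) {
            w <- models[[gsites$motif[k]]]$width
            if (w > 1L)
              interior[(gsites$offset[k] + 2L):(gsites$offset[k] + w)] <- TRUE
          }
        }
        ok <- which(!interior) - 1L  # 0-based boundaries 0..L
        bnd <- sort(sample(ok, min(n_ins, length(ok)), replace = TRUE),
                    decreasing = TRUE)
        who <- sample(informants, length(bnd), replace = TRUE)
        ins_base <- sample(bases, length(bnd), replace = TRUE)
        for (e in seq_along(bnd)) {
          col <- rep("-", nrow(panel))
          names(col) <- panel$species
          col[who[e]] <- ins_base[e]
          b <- bnd[e]
          rows <- cbind(rows[, seq_len(b), drop = FALSE], col,
                        rows[, seq_len(ncol(rows)) > b, drop = FALSE])
        }
      }
      alignments[[gene]] <- setNames(apply(rows, 1, paste, collapse = ""),
                                     panel$species)
    }

    truth$retention <- if (length(retention)) do.call(rbind, retention)
      else data.frame(gene = character(), motif = character(),
                      offset = integer(), species = character(),
                      retained = logical(), stringsAsFactors = FALSE)
    list(alignments = alignments, truth = truth)
  })
}
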
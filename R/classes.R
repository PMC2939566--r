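#' Assign temporal classes from the two cut-disc contrasts
#'
#' Classifies every gene by its (C0_C24, C24_C72) call pattern:
#' * Class I: regulated only in the first 24 h (c1 != flat, c2 = flat);
#' * Class II: regulated only between 24 and 72 h (c1 = flat, c2 != flat);
#' * Class III: significant change between the two periods in opposite
#'   directions (both non-flat, c1 != c2);
#' * Class IV: sustained increase or decrease (c1 = c2 != flat);
#' * none: flat in both.
#' The five labels partition the gene universe.
#'
#' @param results_c1 data.frame from [call_contrast()] for C0_C24.
#' @param results_c2 same for C24_C72; must cover the same genes.
#' @return data.frame `gene`, `c1`, `c2`, `class`.
#' @export
#' @examples
#' r1 <- data.frame(gene = c("a", "b"), call = c("up", "flat"))
#' r2 <- data.frame(gene = c("a", "b"), call = c("down", "flat"))
#' assign_classes(r1, r2)
assign_classes <- function(results_c1, results_c2) {
  check_same_universe(results_c1$gene, results_c2$gene,
                      c("C0_C24", "C24_C72"))
  c1 <- setNames(results_c1$call, results_c1$gene)
  c2 <- setNames(results_c2$call, results_c2$gene)[names(c1)]
  cls <- classify_pattern(c1, c2)
  data.frame(gene = names(c1), c1 = unname(c1), c2 = unname(c2),
             class = cls, stringsAsFactors = FALSE)
}

classify_pattern <- function(c1, c2) {
  ifelse(c1 != "flat" & c2 == "flat", "I",
  ifelse(c1 == "flat" & c2 != "flat", "II",
  ifelse(c1 != "flat" & c2 != "flat" & c1 != c2, "III",
  ifelse(c1 != "flat" & c1 == c2, "IV", "none"))))
}

check_same_universe <- function(a, b, labels) {
  miss_b <- setdiff(a, b)
  miss_a <- setdiff(b, a)
  if (length(miss_b) || length(miss_a)) {
    msg <- c(
      if (length(miss_b)) paste0("missing from ", labels[2], ": ",
        paste(head(miss_b, 10), collapse = ", "),
        if (length(miss_b) > 10) " ..."),
      if (length(miss_a)) paste0("missing from ", labels[1], ": ",
        paste(head(miss_a, 10), collapse = ", "),
        if (length(miss_a) > 10) " ..."))
    stop("missing-gene error: gene universes differ; ",
         paste(msg, collapse = "; "))
  }
  invisible(TRUE)
}

#' Early-regeneration signature: regulated only in cut discs
#'
#' Genes called up (resp. down) in the cut C0_C24 contrast that are flat
#' in the uncut NC0_NC24 contrast. Genes regulated in the uncut discs in
#' either direction are excluded: "only in cut" is read as absent from
#' the uncut differential-expression lists entirely.
#'
#' @param results_cut [call_contrast()] output for C0_C24.
#' @param results_uncut same for NC0_NC24; same gene universe.
#' @return list with character vectors `up_only` and `down_only`.
#' @export
early_signature <- function(results_cut, results_uncut) {
  check_same_universe(results_cut$gene, results_uncut$gene,
                      c("C0_C24", "NC0_NC24"))
  uncut <- setNames(results_uncut$call, results_uncut$gene)
  flat_uncut <- results_cut$gene[uncut[results_cut$gene] == "flat"]
  list(
    up_only = intersect(results_cut$gene[results_cut$call == "up"],
                        flat_uncut),
    down_only = intersect(results_cut$gene[results_cut$call == "down"],
                          flat_uncut))
}

#' Per-direction class composition tables
#'
#' Bookkeeping of up/down/total counts per contrast plus, for each
#' contrast direction, the class breakdown with nearest-integer
#' percentages of that direction's total. A gene contributes to the
#' C0_C24 "up" row when c1 = up, and to the C24_C72 "up" row when
#' c2 = up, so each class is reported against both possible denominators.
#'
#' @param assignments data.frame from [assign_classes()].
#' @param extra_contrasts optional named list of further
#'   [call_contrast()] results (e.g. `NC0_NC24`) whose up/down totals are
#'   appended to the totals table.
#' @return Object of class `regen_composition`: list with `totals`
#'   (contrast, up, down, total) and `classes` (contrast, direction,
#'   class, count, percent).
#' @export
composition_report <- function(assignments, extra_contrasts = NULL) {
  totals <- data.frame(contrast = character(), up = integer(),
                       down = integer(), total = integer(),
                       stringsAsFactors = FALSE)
  classes <- data.frame(contrast = character(), direction = character(),
                        class = character(), count = integer(),
                        percent = integer(), stringsAsFactors = FALSE)
  cols <- c(C0_C24 = "c1", C24_C72 = "c2")
  for (ct in names(cols)) {
    calls <- assignments[[cols[[ct]]]]
    up_n <- sum(calls == "up"); down_n <- sum(calls == "down")
    totals <- rbind(totals, data.frame(
      contrast = ct, up = up_n, down = down_n, total = up_n + down_n,
      stringsAsFactors = FALSE))
    for (dir in c("up", "down")) {
      in_dir <- calls == dir
      denom <- sum(in_dir)
      for (lab in c("I", "II", "III", "IV")) {
        cnt <- sum(in_dir & assignments$class == lab)
        if (cnt == 0) next
        classes <- rbind(classes, data.frame(
          contrast = ct, direction = dir, class = lab, count = cnt,
          percent = as.integer(round(100 * cnt / denom)),
          stringsAsFactors = FALSE))
      }
    }
  }
  for (ct in names(extra_contrasts)) {
    calls <- extra_contrasts[[ct]]$call
    up_n <- sum(calls == "up"); down_n <- sum(calls == "down")
    totals <- rbind(totals, data.frame(
      contrast = ct, up = up_n, down = down_n, total = up_n + down_n,
      stringsAsFactors = FALSE))
  }
  structure(list(totals = totals, classes = classes),
            class = "regen_composition")
}

#' @export
print.regen_composition <- function(x, ...) {
  cat("Direction totals per contrast:\n")
  print(x$totals, row.names = FALSE)
  cat("\nClass composition (percent of the direction total):\n")
  print(x$classes, row.names = FALSE)
  invisible(x)
}
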
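#' Category map: gene categories over a gene universe
#'
#' @param categories named list of character vectors (category id ->
#'   member gene ids). Empty categories are rejected; members must lie in
#'   the universe.
#' @param universe character vector of all gene ids.
#' @return Object of class `category_map` with `$categories`, `$universe`.
#' @export
category_map <- function(categories, universe) {
  if (!is.list(categories) || is.null(names(categories)) ||
      any(!nzchar(names(categories))))
    stop("categories must be a named list")
  universe <- unique(as.character(universe))
  for (nm in names(categories)) {
    members <- unique(as.character(categories[[nm]]))
    if (length(members) == 0) stop("empty category: ", nm)
    bad <- setdiff(members, universe)
    if (length(bad))
      stop("category ", nm, " has members outside the universe: ",
           paste(head(bad, 5), collapse = ", "))
    categories[[nm]] <- members
  }
  structure(list(categories = categories, universe = universe),
            class = "category_map")
}

#' Read categories from a 2-column TSV or a GMT file
#'
#' TSV: columns category, gene (no header). GMT: one line per category,
#' tab-separated `category <TAB> description <TAB> member...`.
#'
#' @param path file path; `.gmt` extension selects GMT parsing.
#' @param universe gene universe; defaults to the union of all members.
#' @return A [category_map()].
#' @export
read_categories <- function(path, universe = NULL) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    cats <- setNames(lapply(parts, function(p) p[-(1:2)]),
                     vapply(parts, `[[`, "", 1))
  } else {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    cats <- split(df[[2]], df[[1]])
  }
  category_map(cats, universe %||% unique(unlist(cats)))
}

#' Whole-genome fold enrichment with hypergeometric significance
#'
#' For every category: k hits in the gene list, list size n, category
#' size K, universe size N; fold = (k/n)/(K/N); p is the hypergeometric
#' upper tail P(X >= k). Only categories with at least `min_genes` hits
#' and p below `p_threshold` are reported (defaults: 5 genes, p < 0.001),
#' sorted by p.
#'
#' @param gene_list character vector, subset of the universe.
#' @param categories a [category_map()].
#' @param min_genes minimum hits for a category to be reported.
#' @param p_threshold maximum hypergeometric p to be reported.
#' @return data.frame `category`, `k`, `n`, `K`, `N`, `fold`, `p`.
#' @export
fold_enrichment <- function(gene_list, categories, min_genes = 5,
                            p_threshold = 0.001) {
  stopifnot(inherits(categories, "category_map"))
  gene_list <- unique(as.character(gene_list))
  if (length(gene_list) == 0) stop("gene list is empty")
  bad <- setdiff(gene_list, categories$universe)
  if (length(bad))
    stop("gene list contains genes outside the universe: ",
         paste(head(bad, 5), collapse = ", "))
  N <- length(categories$universe)
  n <- length(gene_list)
  rows <- lapply(names(categories$categories), function(nm) {
    members <- categories$categories[[nm]]
    K <- length(members)
    k <- length(intersect(gene_list, members))
    data.frame(category = nm, k = k, n = n, K = K, N = N,
               fold = (k / n) / (K / N),
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$k >= min_genes & out$p < p_threshold, , drop = FALSE]
  out <- out[order(out$p, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank genes by the difference of expression values
#'
#' Ranking metric for the running-sum enrichment score: per-gene value in
#' condition A minus condition B, sorted in descending order with ties
#' broken lexicographically by gene id.
#'
#' @param expr_a,expr_b named numeric vectors over the same gene universe
#'   (e.g. mean log2 ratios of two contrasts).
#' @return data.frame `gene`, `metric`, in ranked order.
#' @export
rank_genes <- function(expr_a, expr_b) {
  check_same_universe(names(expr_a), names(expr_b),
                      c("condition A", "condition B"))
  metric <- expr_a - expr_b[names(expr_a)]
  ord <- order(-metric, names(metric), method = "radix")
  data.frame(gene = names(metric)[ord], metric = unname(metric)[ord],
             stringsAsFactors = FALSE)
}

#' Running-sum enrichment score with gene-set permutation p-value
#'
#' Walks down the ranked list adding `1/Nhit` at category members and
#' subtracting `1/Nmiss` elsewhere (unweighted walk; the cumulative sum
#' ends at exactly zero). ES is the signed value of the extremum of
#' largest magnitude. Significance is the fraction of `n_perm` random
#' same-size gene sets with `|ES_perm| >= |ES|` (add-one smoothing).
#' The optional weighted variant multiplies member increments by
#' `|metric|` (normalized to sum to 1 over members).
#'
#' @param ranked data.frame from [rank_genes()] (or a character vector of
#'   gene ids; then the zero-cross index is `NA`).
#' @param members character vector, nonempty proper subset of the list.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation null.
#' @param weighted logical; classic metric-weighted increments instead of
#'   the unweighted walk (default `FALSE`).
#' @return Object of class `regen_gsea`: list with `ES`, `p_perm`,
#'   `zero_cross_index` (count of positive metrics), `hit_positions`,
#'   `running_sum`, `n_perm`, `seed`.
#' @export
#' @examples
#' ranked <- data.frame(gene = letters[1:10], metric = 5:-4)
#' gsea_es(ranked, c("a", "b", "e"), n_perm = 100, seed = 1)$ES
gsea_es <- function(ranked, members, n_perm = 1000, seed = 1,
                    weighted = FALSE) {
  if (is.character(ranked))
    ranked <- data.frame(gene = ranked, metric = NA_real_,
                         stringsAsFactors = FALSE)
  genes <- ranked$gene
  members <- unique(members)
  if (length(members) == 0) stop("category is empty")
  if (!all(members %in% genes))
    stop("category members missing from the ranked list: ",
         paste(head(setdiff(members, genes), 5), collapse = ", "))
  if (length(members) >= length(genes))
    stop("category must be a proper subset of the ranked list")

  hits <- genes %in% members
  walk_es <- function(hits) {
    n_hit <- sum(hits); n_miss <- length(hits) - n_hit
    if (weighted) {
      w <- abs(ranked$metric)
      w[!hits] <- 0
      tot <- sum(w)
      inc <- if (tot > 0) w / tot else as.numeric(hits) / n_hit
      return(cumsum(ifelse(hits, inc, -1 / n_miss)))
    }
    # exact scaled-integer walk: member step n_miss, miss step -n_hit,
    # normalized once -- the sum ends at exactly zero and extremum ties
    # are decided in exact arithmetic
    cumsum(ifelse(hits, n_miss, -n_hit)) / (n_hit * n_miss)
  }
  pick_es <- function(rs) {
    mx <- max(rs); mn <- min(rs)
    if (mx >= -mn) mx else mn  # ties go to the positive tail
  }
  rs <- walk_es(hits)
  es <- pick_es(rs)

  m <- sum(hits); N <- length(genes)
  perm_abs <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      h <- logical(N)
      h[sample.int(N, m)] <- TRUE
      abs(pick_es(walk_es(h)))
    }, numeric(1))
  })
  p_perm <- (1 + sum(perm_abs >= abs(es))) / (n_perm + 1)

  structure(list(
    ES = es, p_perm = p_perm,
    zero_cross_index = if (all(is.na(ranked$metric))) NA_integer_
      else sum(ranked$metric > 0),
    hit_positions = which(hits), running_sum = rs,
    n_perm = n_perm, seed = seed, weighted = weighted
  ), class = "regen_gsea")
}

#' @export
print.regen_gsea <- function(x, ...) {
  cat(sprintf(
    "running-sum enrichment: ES = %.4f, permutation p = %.4g (%d perms)\n",
    x$ES, x$p_perm, x$n_perm))
  if (!is.na(x$zero_cross_index))
    cat(sprintf("  zero cross after position %d of %d\n",
                x$zero_cross_index, length(x$running_sum)))
  invisible(x)
}
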
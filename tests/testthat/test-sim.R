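# Synthetic data generator: determinism, planted structure, round trips,
# closed-form background rates, alignment retention statistics.

test_that("identical configs give bit-identical outputs", {
  cfg <- sim_config(n_genes = 40, promoter_length = 150, seed = 5)
  a <- generate_expression(cfg)
  b <- generate_expression(cfg)
  expect_identical(a, b)
  pa <- generate_promoters(cfg, a$truth)
  pb <- generate_promoters(cfg, b$truth)
  expect_identical(as.character(pa$promoters), as.character(pb$promoters))
  expect_identical(pa$annotation, pb$annotation)
  aa <- generate_alignments(cfg, pa$truth, pa$promoters)
  ab <- generate_alignments(cfg, pb$truth, pb$promoters)
  expect_identical(aa$alignments, ab$alignments)
  expect_identical(aa$truth$retention, ab$truth$retention)
})

test_that("a zero effect plants nothing and the truth is all flat", {
  cfg <- sim_config(n_genes = 30, effect_size_log2 = 0, seed = 2)
  sim <- generate_expression(cfg)
  expect_true(all(sim$truth$genes$class == "none"))
  expect_true(all(sim$truth$genes$dir_c1 == 0))
  # replicate values are pure noise around 0 (after dye-swap correction)
  corr <- normalize_replicates(sim$expr$C0_C24, cfg$dye_swap_pattern)
  expect_lt(abs(mean(corr)), 4 * cfg$noise_sd_log2 / sqrt(length(corr)))
})

test_that("planted-up replicate means behave as frozen by the brute-force run", {
  # frozen regression values from an independent re-simulation with the
  # same RNG stream: 41 planted-up genes, all with replicate mean > 1
  cfg <- sim_config(n_genes = 1000, effect_size_log2 = 2,
                    noise_sd_log2 = 0.3, seed = 7)
  sim <- generate_expression(cfg)
  flip <- ifelse(cfg$dye_swap_pattern, -1, 1)
  corr <- sweep(sim$expr$C0_C24, 2, flip, "*")
  up <- sim$truth$genes$dir_c1 == 1
  expect_identical(sum(up), 41L)
  expect_equal(mean(rowMeans(corr[up, ]) > 1), 1)
})

test_that("dye-swapped replicates are stored sign-flipped", {
  cfg <- sim_config(n_genes = 200, noise_sd_log2 = 0.05, seed = 9)
  sim <- generate_expression(cfg)
  up <- sim$truth$genes$dir_c1 == 1
  raw <- sim$expr$C0_C24
  # swap replicates (2 and 4 by default) carry the opposite sign
  expect_true(all(raw[up, 2] < 0) && all(raw[up, 1] > 0))
})

test_that("every planted motif is rediscovered at its recorded offset and strand", {
  cfg <- sim_config(n_genes = 60, promoter_length = 250,
                    planted_motif_rate_target = 1,
                    planted_motif_rate_background = 0.5, seed = 13)
  sim <- generate_expression(cfg)
  pro <- generate_promoters(cfg, sim$truth)
  planted <- pro$truth$planted_sites
  expect_gt(nrow(planted), 20)
  for (m in cfg$motif_models) {
    hits <- scan_motif(pro$promoters, m)
    pl <- planted[planted$motif == m$name, , drop = FALSE]
    found <- paste(pl$gene, pl$offset, pl$strand) %in%
      paste(hits$gene, hits$offset, hits$strand)
    expect_true(all(found))
  }
})

test_that("minus-strand promoters follow the reverse-complement convention", {
  cfg <- sim_config(n_genes = 6, promoter_length = 80, seed = 21)
  sim <- generate_expression(cfg)
  pro <- generate_promoters(cfg, sim$truth)
  minus <- which(pro$annotation$strand == "-")
  expect_gt(length(minus), 0)
  for (i in minus) {
    chr <- as.character(pro$genome[[pro$annotation$chrom[i]]])
    t0 <- pro$annotation$start[i]
    window <- substr(chr, t0 + 2, t0 + 1 + cfg$promoter_length)
    expect_identical(
      oracle_revcomp(window),
      as.character(pro$promoters[[pro$annotation$gene[i]]]))
  }
})

test_that("unplanted promoters match the closed-form background motif rate", {
  # with planting off, motif occurrences arise only by chance; the
  # expected count is n * (L - w + 1) * p_match with p_match enumerated
  # over all 4^w windows (either-strand match, post-collapse)
  cfg <- sim_config(n_genes = 10000, promoter_length = 250,
                    planted_motif_rate_target = 0,
                    planted_motif_rate_background = 0, seed = 31)
  sim <- generate_expression(cfg)
  pro <- generate_promoters(cfg, sim$truth)
  expect_identical(nrow(pro$truth$planted_sites), 0L)
  for (m in cfg$motif_models) {
    w <- m$width
    bases <- c("A", "C", "G", "T")
    grid <- do.call(expand.grid,
                    c(rep(list(bases), w), stringsAsFactors = FALSE))
    wins <- do.call(paste0, grid)
    cons <- m$consensus
    match_any <- vapply(wins, function(win) {
      nrow(oracle_scan(win, cons)) > 0
    }, logical(1))
    p_match <- mean(match_any)
    expected <- cfg$n_genes * (cfg$promoter_length - w + 1) * p_match
    observed <- nrow(scan_motif(pro$promoters, m))
    expect_lt(abs(observed - expected), 3 * sqrt(expected))
  }
})

test_that("perfect conservation reproduces the reference row everywhere", {
  cfg <- sim_config(n_genes = 10, promoter_length = 120,
                    per_branch_retention = 1, retention_rank_decay = 0,
                    align_background_mutation = 0, align_gap_rate = 0,
                    seed = 8)
  sim <- generate_expression(cfg)
  pro <- generate_promoters(cfg, sim$truth)
  aln <- generate_alignments(cfg, pro$truth, pro$promoters)
  for (gene in names(aln$alignments)) {
    rows <- aln$alignments[[gene]]
    expect_true(all(rows == rows[[1]]))
    expect_identical(rows[[1]], as.character(pro$promoters[[gene]]))
  }
})

test_that("zero retention leaves no planted site conserved", {
  cfg <- sim_config(n_genes = 30, promoter_length = 150,
                    planted_motif_rate_target = 1,
                    planted_motif_rate_background = 1,
                    per_branch_retention = 0, seed = 14)
  sim <- generate_expression(cfg)
  pro <- generate_promoters(cfg, sim$truth)
  aln <- generate_alignments(cfg, pro$truth, pro$promoters)
  expect_true(all(!aln$truth$retention$retained))
  for (m in cfg$motif_models) {
    hits <- scan_motif(pro$promoters, m)
    hits <- conservation_filter(hits, m, aln$alignments,
                                cfg$species_panel, min_species = 1)
    pl <- pro$truth$planted_sites
    pl <- pl[pl$motif == m$name, , drop = FALSE]
    planted_hits <- hits[paste(hits$gene, hits$offset) %in%
                           paste(pl$gene, pl$offset), , drop = FALSE]
    expect_true(all(!planted_hits$passes_conservation))
  }
})

test_that("site retention counts match the per-species binomial expectation", {
  cfg <- sim_config(n_genes = 500, promoter_length = 60,
                    planted_motif_rate_target = 1,
                    planted_motif_rate_background = 1,
                    per_branch_retention = 0.8, seed = 17)
  sim <- generate_expression(cfg)
  pro <- generate_promoters(cfg, sim$truth)
  aln <- generate_alignments(cfg, pro$truth, pro$promoters)
  ret <- aln$truth$retention
  n_sites <- nrow(unique(ret[, c("gene", "motif", "offset")]))
  expect_gt(n_sites, 500)
  # brute-force Poisson-binomial tail: P(site conserved in >= 5
  # informants), convolved over the per-species retention probabilities
  p_s <- cfg$per_branch_retention ^
    (1 + cfg$retention_rank_decay * (cfg$species_panel$rank[-1] - 1))
  pmf <- 1
  for (p in p_s) pmf <- convolve_bernoulli(pmf, p)
  p_ge5 <- sum(pmf[seq_along(pmf) - 1 >= 5])
  per_site <- tapply(ret$retained, paste(ret$gene, ret$motif, ret$offset),
                     sum)
  observed <- sum(per_site >= 5)
  expected <- n_sites * p_ge5
  expect_lt(abs(observed - expected),
            3 * sqrt(n_sites * p_ge5 * (1 - p_ge5)))
})
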
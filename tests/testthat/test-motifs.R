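# Promoter extraction, IUPAC/PWM scanning, conservation filtering.

test_that("promoter coordinates follow the 0-based half-open convention", {
  chr <- rand_dna(1200)
  genome <- Biostrings::DNAStringSet(c(chrX = chr))
  ann <- data.frame(chrom = "chrX", start = 1000L, end = 1001L,
                    gene = "g1", score = 0L, strand = "+",
                    stringsAsFactors = FALSE)
  pr <- extract_promoters(genome, ann, length = 1000)
  expect_identical(as.character(pr[["g1"]]), substr(chr, 1, 1000))
})

test_that("promoters truncate at contig edges with a warning", {
  chr <- rand_dna(600)
  genome <- Biostrings::DNAStringSet(c(chrX = chr))
  ann <- data.frame(chrom = "chrX", start = 500L, end = 501L,
                    gene = "g1", score = 0L, strand = "+",
                    stringsAsFactors = FALSE)
  expect_warning(pr <- extract_promoters(genome, ann, length = 1000),
                 "truncated")
  expect_identical(as.character(pr[["g1"]]), substr(chr, 1, 500))
})

test_that("a TSS outside its contig is an error record, not a stop", {
  genome <- Biostrings::DNAStringSet(c(chrX = rand_dna(100)))
  ann <- data.frame(chrom = c("chrX", "chrX"), start = c(50L, 500L),
                    end = c(51L, 501L), gene = c("ok", "bad"),
                    score = 0L, strand = "+", stringsAsFactors = FALSE)
  suppressWarnings(pr <- extract_promoters(genome, ann, length = 40))
  expect_identical(names(pr), "ok")
  expect_identical(attr(pr, "errors")$gene, "bad")
})

test_that("IUPAC scanning finds the worked examples", {
  pr <- Biostrings::DNAStringSet(c(g1 = "AACACGTGTT"))
  hits <- scan_motif(pr, motif_model("Ebox", consensus = "CACGTG"))
  expect_identical(nrow(hits), 1L)  # palindrome reported once
  expect_identical(hits$offset, 2L)
  expect_identical(hits$strand, "+")

  ap1 <- motif_model("AP1", consensus = "TGASTCA")
  pr2 <- Biostrings::DNAStringSet(
    c(a = "TGACTCA", b = "TGAGTCA", c = "TGATTCA"))
  hits2 <- scan_motif(pr2, ap1)
  expect_setequal(hits2$gene, c("a", "b"))  # S = C/G, never T
})

test_that("scanner output equals the brute-force sliding-window oracle", {
  set.seed(47)
  motifs <- c("CACGTG", "TGASTCA", "RYGCNA", "TTAAW", "ACGGTA")
  for (case in 1:500) {
    L <- sample(10:50, 1)
    seq <- rand_dna(L)
    cons <- sample(motifs, 1)
    pr <- Biostrings::DNAStringSet(setNames(seq, "g"))
    got <- scan_motif(pr, motif_model("m", consensus = cons))
    want <- oracle_scan(seq, cons)
    expect_identical(got$offset, want$offset)
    expect_identical(got$strand, want$strand)
    expect_identical(got$match, want$match)
  }
})

test_that("palindrome scans are coordinate-mirrored on the reverse complement", {
  set.seed(53)
  model <- motif_model("Ebox", consensus = "CACGTG")
  for (case in 1:20) {
    L <- sample(30:80, 1)
    seq <- rand_dna(L)
    # salt with a couple of planted boxes
    for (o in sample(L - 6, 2)) {
      substr(seq, o, o + 5) <- "CACGTG"
    }
    fw <- scan_motif(Biostrings::DNAStringSet(c(g = seq)), model)
    rv <- scan_motif(Biostrings::DNAStringSet(
      c(g = oracle_revcomp(seq))), model)
    expect_setequal(rv$offset, L - 6 - fw$offset)
  }
})

test_that("PWM mode reproduces consensus hits at a strict threshold", {
  # PWM built from unambiguous counts behaves like the exact consensus
  counts <- matrix(0, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(6))
    counts[c("C", "A", "C", "G", "T", "G")[j], j] <- 10
  model <- motif_model("EboxPWM", pwm = counts, score_threshold = 0.999)
  seqs <- Biostrings::DNAStringSet(c(g1 = "AACACGTGTT", g2 = rand_dna(30)))
  hits <- scan_motif(seqs, model)
  want <- scan_motif(seqs, motif_model("Ebox", consensus = "CACGTG"))
  expect_identical(hits$gene, want$gene)
  expect_identical(hits$offset, want$offset)
  expect_gt(min(hits$score), 0)
})

test_that("PWM text files round-trip through read_pwm", {
  path <- tempfile(fileext = ".pwm")
  writeLines(c("A  0 10  0  0", "C 10  0 10  0", "G  0  0  0 10",
               "T  0  0  0  0"), path)
  m <- read_pwm(path, name = "toy")
  expect_identical(m$mode, "pwm")
  expect_identical(m$width, 4L)
  hits <- scan_motif(Biostrings::DNAStringSet(c(g = "AACACGTT")), m)
  expect_true(2L %in% hits$offset)  # CACG at 0-based offset 2

  # the shipped synthetic AP1 count matrix behaves like its consensus
  shipped <- system.file("extdata", "ap1_synthetic_counts.pwm",
                         package = "regenprofiler")
  ap1 <- read_pwm(shipped, name = "AP1_synthetic",
                  score_threshold = 0.99)
  seqs <- Biostrings::DNAStringSet(
    c(g = "AATGACTCATT", h = "AATGAGTCATT", i = "AATGATTCATT"))
  got <- scan_motif(seqs, ap1)
  expect_setequal(got$gene, c("g", "h"))  # S = C/G only
  expect_identical(unique(got$offset), 2L)
})

test_that("conservation requires enough informants including a distal one", {
  model <- motif_model("Ebox", consensus = "CACGTG")
  panel <- default_species_panel()
  prom <- paste0("AAAA", "CACGTG", "TTTT")
  informants <- panel$species[-1]
  make_aln <- function(conserved_in) {
    rows <- vapply(c(panel$species[1], informants), function(s) {
      if (s == panel$species[1] || s %in% conserved_in) prom
      else paste0("AAAA", "AAAAAA", "TTTT")
    }, character(1))
    list(g = rows)
  }
  sites <- scan_motif(Biostrings::DNAStringSet(c(g = prom)), model)
  # conserved in all informants -> passes
  r <- conservation_filter(sites, model, make_aln(informants), panel)
  expect_true(all(r$passes_conservation))
  # five proximal informants, none distal -> fails under require_distal
  proximal5 <- c("Dsim", "Dsec", "Dyak", "Dere", "Dana")
  r2 <- conservation_filter(sites, model, make_aln(proximal5), panel)
  expect_false(any(r2$passes_conservation))
  r3 <- conservation_filter(sites, model, make_aln(proximal5), panel,
                            require_distal = FALSE)
  expect_true(all(r3$passes_conservation))
  # four informants incl. a distal one -> still fails min_species = 5
  r4 <- conservation_filter(sites, model,
                            make_aln(c("Dsim", "Dyak", "Dana", "Dpse")),
                            panel)
  expect_false(any(r4$passes_conservation))
  # demanding D. pseudoobscura itself
  with_pse <- c("Dsim", "Dsec", "Dyak", "Dere", "Dpse")
  no_pse <- c("Dsim", "Dsec", "Dyak", "Dere", "Dvir")
  r5 <- conservation_filter(sites, model, make_aln(with_pse), panel,
                            require_pseudoobscura = "Dpse")
  expect_true(all(r5$passes_conservation))
  r6 <- conservation_filter(sites, model, make_aln(no_pse), panel,
                            require_pseudoobscura = "Dpse")
  expect_false(any(r6$passes_conservation))
})

test_that("conservation flags equal a brute-force recomputation on generator output", {
  cfg <- sim_config(n_genes = 80, promoter_length = 200,
                    planted_motif_rate_target = 1,
                    planted_motif_rate_background = 0.5,
                    per_branch_retention = 0.7, seed = 37)
  sim <- generate_expression(cfg)
  pro <- generate_promoters(cfg, sim$truth)
  aln <- generate_alignments(cfg, pro$truth, pro$promoters)
  for (m in cfg$motif_models) {
    sites <- scan_motif(pro$promoters, m)
    got <- conservation_filter(sites, m, aln$alignments,
                               cfg$species_panel)
    distal <- cfg$species_panel$species[cfg$species_panel$distal]
    for (i in seq_len(nrow(got))) {
      rows <- aln$alignments[[got$gene[i]]]
      refchars <- strsplit(rows[[1]], "")[[1]]
      cols <- which(refchars != "-")
      span <- cols[got$offset[i] + 1]:cols[got$offset[i] + m$width]
      conserved <- character(0)
      for (s in names(rows)[-1]) {
        sub <- strsplit(rows[[s]], "")[[1]][span]
        sub <- paste(sub[sub != "-"], collapse = "")
        ok <- nrow(oracle_scan(sub, m$consensus)) > 0
        if (ok) conserved <- c(conserved, s)
      }
      expect_identical(got$n_conserved[i], length(conserved))
      expect_identical(got$passes_conservation[i],
                       length(conserved) >= 5 &&
                         any(conserved %in% distal))
    }
  }
})

test_that("raising min_species never gains passing sites", {
  cfg <- sim_config(n_genes = 40, promoter_length = 150,
                    planted_motif_rate_target = 1,
                    planted_motif_rate_background = 0.6,
                    per_branch_retention = 0.6, seed = 41)
  sim <- generate_expression(cfg)
  pro <- generate_promoters(cfg, sim$truth)
  aln <- generate_alignments(cfg, pro$truth, pro$promoters)
  m <- cfg$motif_models[[1]]
  sites <- scan_motif(pro$promoters, m)
  passing <- vapply(1:12, function(k) {
    sum(conservation_filter(sites, m, aln$alignments, cfg$species_panel,
                            min_species = k)$passes_conservation)
  }, numeric(1))
  expect_true(all(diff(passing) <= 0))
})

test_that("promoters shorter than the motif are skipped with a warning", {
  pr <- Biostrings::DNAStringSet(c(tiny = "ACG", ok = "AACACGTGTT"))
  expect_warning(
    hits <- scan_motif(pr, motif_model("Ebox", consensus = "CACGTG")),
    "skipping")
  expect_identical(unique(hits$gene), "ok")
})
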
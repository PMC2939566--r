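---
title: "Profiling the regeneration transcriptome of fragmented wing imaginal discs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the regeneration transcriptome of fragmented wing imaginal discs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regenprofiler)
```

## The biological setting and the model

When a *Drosophila* wing imaginal disc is fragmented and cultured in an
adult host, the wound heals and a blastema of proliferating cells
rebuilds the missing tissue over roughly three days. The transcriptional
programme behind this is followed here through three pairwise two-colour
microarray contrasts: `NC0_NC24` (intact, implanted discs — the
implantation control), `C0_C24` (first 24 h after the cut, wound healing)
and `C24_C72` (24–72 h, blastema proliferation). Every stage of the
analysis consumes or produces one of a handful of tabular objects:
per-contrast calls, temporal class assignments, enrichment tables,
conserved motif sites, and resampling null distributions.

### Differential expression

The caller is deliberately simple. Each contrast provides replicate
log2 ratios per gene (four hybridizations in dye-swapped pairs by
default). `normalize_replicates()` flips the dye-swapped replicates back
and median-centres every replicate column; `call_contrast()` computes
the mean log2 fold change, a one-sample *t* test against zero, and
Benjamini–Hochberg q-values over all genes of the contrast. A gene is
`up` iff its mean log2FC ≥ 1 (two-fold) with q < 0.05, `down`
symmetrically, otherwise `flat`. Zero-variance genes get p = 0 when the
mean is nonzero and p = 1 otherwise — a deterministic degenerate rule
rather than an exception.

Two choices here were genuinely open and are worth stating. First, a
plain *t* test stands in for a moderated linear-model fit: downstream
stages consume only the {up, down, flat} labels, and at the planted
effect sizes used throughout (2 log2 units against 0.3 log2 units of
noise) the two are indistinguishable in the labels they produce. Second,
the two-fold rule is applied to the mean log2 ratio, not to every
replicate; the replicate-wise variant is strictly more conservative and
can be emulated by raising the threshold.

### Temporal classes

`assign_classes()` reduces each gene to its (C0_C24, C24_C72) call pair:

* **Class I** — regulated only in the first 24 h (wound response);
* **Class II** — regulated only between 24 and 72 h (proliferation
  phase);
* **Class III** — significantly regulated in both periods in *opposite*
  directions (transient injury response, switched off once healing
  completes);
* **Class IV** — sustained regulation in one direction;
* **none** — flat in both.

The five labels provably partition the universe (an exhaustive
9-pattern enumeration in the test suite yields exactly 2/2/2/2/1
patterns). `composition_report()` emits direction totals per contrast
and per-class counts with nearest-integer percentages of each
direction's total; because a Class III gene is, say, up early and down
late, it is reported against both denominators, which is why the same
class can legitimately be "29% of late downregulated" and "8% of early
upregulated" genes. `early_signature()` returns the genes regulated
only in cut discs — a gene non-flat in the uncut contrast in *either*
direction is excluded, reading "only in cut" as absence from the uncut
differential-expression lists entirely.

### Category enrichment, two ways

`fold_enrichment()` compares a gene list against the whole-universe
category frequencies: fold = (k/n)/(K/N) with a hypergeometric
upper-tail p, reporting only categories with at least five hits at
p < 0.001 (both configurable). `gsea_es()` walks a ranked list
(`rank_genes()` ranks by the difference of expression values,
descending, ties broken lexicographically for determinism) and adds
1/N~hit~ at members, subtracting 1/N~miss~ elsewhere. The walk is
computed in exact scaled-integer arithmetic (member step N~miss~, miss
step −N~hit~, normalized once), so the sum returns to exactly zero and
extremum ties are decided exactly, with ties going to the positive
tail. The enrichment score is the signed extremum of largest magnitude;
significance comes from gene-set resampling (random same-size sets),
not phenotype permutation, because the pipeline consumes a single
ranked list rather than replicate phenotypes. The classic
metric-weighted walk is available behind `weighted = TRUE` but is not
the default: the unweighted increment/decrement walk is the variant the
rest of the analysis is built around. The zero-cross index — the
position where the ranking metric changes sign — is reported alongside.

### Promoters, motifs and conservation

`extract_promoters()` takes 1,000 bases upstream of each annotated TSS
(0-based half-open coordinates; minus-strand genes take the reverse
complement of the downstream-in-coordinates window), truncating at
contig edges with a warning. `scan_motif()` matches either a degenerate
IUPAC consensus (exact letter-set match, both strands) or a PWM
(log-odds score ≥ threshold × maximal score). Sites found by both
strands over the identical span with the identical spanned sequence are
collapsed to a single `+` record — without this, every palindromic
E-box (CACGTG) and every pseudo-palindromic AP1 site (TGASTCA) would be
double-counted. All overlapping sites are reported; de-duplication is
left to downstream per-gene statistics.

The shipped defaults are the AP1 consensus TGASTCA and the E-box
CACGTG. The published AP1 position matrix is not redistributed;
`read_pwm()` accepts it (or any JASPAR-style count matrix) for users
who hold it.

`conservation_filter()` implements phylogenetic footprinting over a
12-species panel (reference first, eleven informants in published
phylogenetic order): the alignment columns spanning the reference site
are taken with zero slack by default (configurable ±N columns, since no
canonical mapping rule exists), per-informant gaps are dropped, and the
motif is re-tested on both strands of the resulting subsequence. A site
passes when conserved in ≥ 5 informants including at least one species
flagged distal (*D. pseudoobscura* or more distant). Whether
*D. pseudoobscura itself* must be among them is ambiguous in common
usage; the default accepts any distal species, and
`require_pseudoobscura = "Dpse"` enforces the stricter reading. The
reference species is never counted among the five.

### The resampling Z-test

`ztest_enrichment()` asks whether a gene set carries more conserved
sites than expected: it draws `n_samples` (default 10,000) random
subsets of the same size from the universe of genes with a usable
promoter, computes the chosen burden statistic per draw —
`genes_with_site` (genes with ≥ 1 passing site) or `total_sites`; both
are first-class because either can be the natural summary — and reports
Z = (observed − mean)/sd with the one-sided upper-tail normal p, plus
the empirical tail fraction with add-one smoothing as a
distribution-free companion. Draws are without replacement within a
draw and independent across draws. Small universes can be enumerated
exhaustively (`exhaustive = TRUE`), which the tests use as an oracle. A
zero-variance null is flagged degenerate (p = 1 if observed ≤ mean,
else 0) instead of dividing by zero.

## The synthetic data generator

Real deposited arrays are not required anywhere: `sim_config()` +
`generate_expression()` / `generate_promoters()` /
`generate_alignments()` / `generate_categories()` produce every input
with recorded ground truth, and all stochastic behaviour derives from
one seed via stage-name hashing (`derive_seed()`), so identical
configurations are bit-for-bit reproducible.

What is emulated, and the defaults chosen for it:

* **Expression.** Four replicate log ratios per contrast with dye swaps
  on replicates 2 and 4, planted effects of ±2 log2 units and Gaussian
  noise of 0.3 log2 units. Class proportions default to I 5%, II 2%,
  III 1%, IV 1% of the genome — mirroring a time course in which the
  early contrast regulates an order of magnitude more genes than the
  late one and sign-reversing genes are rare. Half of the early-
  regulated genes are also regulated in the implantation control
  (`nc_shared_fraction`), and 90% of Class III genes follow the
  dominant up-then-down pattern. A zero effect size plants nothing: the
  ground truth is then all flat.
* **Promoters.** Uniform base composition (the simplest null, making
  background match probabilities closed-form: expected chance hits are
  (L − w + 1) · p~match~ with p~match~ enumerable over all 4^w
  windows). Concrete motif instances are planted at 80% of target-class
  genes (Class III by default) and 5% of all others, at uniform random
  offsets and strands, never overlapping. Genes alternate strands and
  each promoter is embedded in a padded contig so that
  `extract_promoters()` on the emitted genome recovers the emitted
  promoters exactly.
* **Alignments.** Per informant, a planted site is retained intact with
  probability 0.9 decaying gently with distance rank
  (0.9^(1+0.15·(rank−1)), ≈ 0.77 for the most distant informant), or
  else deliberately degraded by substituting every site position with a
  base outside the motif's allowed set on either strand — a degraded
  site can never match, so the retention flags are an exact ground
  truth for the conservation filter. Background columns mutate at 20%
  per species; insertion-only gap events (2 per 100 columns in
  expectation) never fall inside a planted site, keeping the
  site-to-column mapping and the conservation oracle closed-form.

What is *not* emulated — and therefore what passing tests do not show
about real arrays: probe-level intensities, intensity-dependent dye
bias (the swap is a pure sign flip), spatial artefacts, correlated
replicates, non-uniform promoter composition, alignment errors, and
binding sites that drift rather than die. The generator validates the
arithmetic and the decision rules, not the noise model of a scanner.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open everywhere internally; BED output
  stays 0-based.
* The running sum is exact (scaled integers); the end-at-zero assertion
  uses 1e−12 only as a formality.
* Ranking ties and site ordering are broken lexicographically so every
  output is deterministic.
* Genes missing from one contrast are an error listing the offenders,
  never silently coerced to flat — silent coercion hides broken joins.
* Empty categories, empty gene lists, categories equal to the universe,
  non-positive CT values and probability parameters outside [0, 1] are
  all rejected with explicit messages.

## Problem sizes used by the checks

The test-suite and acceptance-script simulations run at desk scale,
chosen as the smallest sizes at which every statistical check is
comfortably powered: 300–1,000 genes per simulated genome, 200–500 bp
promoters where the promoter length itself is not under test, 400–1,000
resampling draws inside calibration loops, 100 seeds for the power
check and 1,000 seeded runs for type-I-error calibration. The planted
signal (80% motif rate in Class III genes against a 5% background with
0.9 retention) gives the Z-test essentially complete power at these
sizes, which the acceptance suite verifies rather than assumes.

## Limitations

* The caller is a stand-in: no within-array normalization beyond median
  centring, no moderated variance, no probe-to-gene collapsing.
* Conservation is presence/absence of a motif match in aligned columns;
  no use of continuous conservation scores, no tolerance for sites that
  shift position between species beyond the configurable column slack.
* The Z-test's normal-approximation p is anti-conservative for very
  small, very discrete burden statistics; the empirical p is reported
  alongside and should be preferred when the observed set has fewer
  than ~10 genes.
* GO-style categories are supplied as input tables; there is no
  ontology propagation.

## A short worked run

```{r example, eval = FALSE}
cfg <- run_config(mode = "synthetic", seed = 42,
                  out_dir = "regen_run",
                  sim = list(n_genes = 600, promoter_length = 500),
                  enrich = list(n_perm = 500),
                  ztest = list(n_samples = 5000))
res <- run_pipeline(cfg)
res$composition          # direction totals and class percentages
subset(res$ztests, gene_set == "class_III")  # planted-motif Z-test
```

The run directory then holds the calls per contrast, `classes.tsv`,
the composition tables, enrichment tables, `conserved_sites.tsv`,
`ztest.tsv` and a `manifest.json` whose digests make the run
reproducible byte for byte.
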
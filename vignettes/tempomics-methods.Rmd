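---
title: "Models and methods behind tempomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tempomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

tempomics analyses paired bulk RNA-seq and ATAC-seq time courses: weekly
samples across a developmental window, unequal replicate numbers between
the two assays, and a per-sample RNA quality covariate (RIN). This
vignette explains the statistical models, the choices made where the
design was genuinely open, and what the synthetic-data generator does and
does not emulate.

## The time-course model

Counts for feature $i$ in sample $j$ are modeled as negative binomial with
mean $\mu_{ij}$ and dispersion $\alpha_i$
($\mathrm{Var} = \mu + \alpha\mu^2$), with a log link:

$$\log \mu_{ij} = \beta_{i0} + \beta_{iRIN} x_{jRIN} + \beta_{iTP} x_{jTP} + \log s_j$$

Timepoints are reference-coded with the earliest timepoint as baseline
(this makes pairwise Wald contrasts directly interpretable), and the size
factor $s_j$ — median of ratios across always-expressed features — enters
as an offset. The reduced model keeps only RIN. A likelihood-ratio test of
full versus reduced isolates the temporal signal from quality variation;
for ATAC data, where no quality covariate is measured, the reduced model
is intercept-only. All-zero features are excluded before fitting because
their likelihood carries no information about the coefficients.

### Dispersion handling and calibration

Three decisions here are the numerically load-bearing ones.

1. **Cox–Reid adjustment.** The per-feature dispersion is the maximizer of
   the *adjusted* profile likelihood
   $\ell(\alpha) - \tfrac12 \log\det(X^TWX)$ under the full model. The
   unadjusted profile MLE is biased downward because the fitted
   coefficients absorb noise; in our null simulations that bias roughly
   doubled the nominal test size.
2. **Moderation.** Per-feature estimates are shrunk toward the
   cross-feature median on the log scale with weight
   $d_{res}/(d_{res}+d_0)$, $d_0 = 10$ prior degrees of freedom. With
   6–9 replicates per timepoint the data dominate; with the minimal
   2-replicate ATAC design (4 residual df) the ensemble dominates, which
   is the only way that design yields a usable test at all. The tradeoff
   is deliberate: genes whose true dispersion sits in the tails of the
   ensemble are slightly mis-calibrated individually.
3. **F reference.** Because the dispersion is estimated, not known, the
   LRT statistic divided by its df is referred to an
   $F(\mathrm{df}, d_{res}+d_0)$ distribution rather than $\chi^2$.
   An underestimated dispersion inflates the statistic much more than an
   overestimated one deflates it, so even unbiased dispersion noise makes
   the plain $\chi^2$ test anticonservative. The bare `nb_lrt()`
   operation, which compares two fits at a *fixed* shared dispersion,
   keeps the $\chi^2$ reference.

The package validates this scheme by simulation rather than by matching
any external tool: under a 2,000-feature null with a genuine RIN effect,
the fraction of raw $p < 0.05$ falls in the low 0.05s and the KS distance
to uniform is below 0.02 (see `tests/testthat/test-acceptance.R`).

Independent filtering scans mean-normalized-count quantile thresholds
(0–0.95 in steps of 0.01), smooths the BH rejection counts with a
centered moving average of window 5, and keeps the threshold maximizing
smoothed rejections at $\alpha = 0.05$; features below it get no adjusted
p. The grid and smoothing window are conventional choices — the procedure
is insensitive to them on our data because the rejection curve is flat
near its maximum.

## Consensus peaks

Peak calls are 0-based half-open; overlap means at least one shared base,
so an interval abutting a blacklist region survives filtering. Calls
overlapping the blacklist or the naked-DNA control peaks are removed
first, then overlapping calls are merged and a merged region is kept only
if *every* replicate of at least one timepoint contributes a call — the
stringent reproducibility rule that trades false negatives for a clean
set. Timepoints left with a single replicate are excluded (with a
warning) rather than silently weakening the rule. The emitted peak is
exactly 500 bp around the representative summit: the summit of the
highest-scoring supporting call, ties broken to the leftmost, which makes
the output deterministic. Fragment counting assigns a fragment to a peak
when its midpoint lies in the half-open interval — unambiguous at peak
borders, at the cost of ignoring fragments straddling an edge.

## Annotation

Distances are summit-to-TSS, strand-aware (positive = downstream in the
gene's orientation). "Nearest gene" is interpreted as nearest *TSS*, with
assignment capped at ±50 kb and ties broken to the smaller gene id. The
promoter window defaults to −3000/+3000 bp around the TSS and the
downstream window to 3 kb, both configurable; categories follow the
precedence promoter > 5′ UTR > 3′ UTR > exon > intron > downstream >
distal intergenic, so every peak receives exactly one category and the
category partition always sums to the peak count.

## Modules

For clustering, counts of significant features go through CPM,
log2(x + 1), column quantile normalization (ties receive the average of
the tied ranks' reference values), then row z-scoring. Quantile
normalization is applied on the log scale and z-scoring must come last to
produce the displayed z units; the chain is invariant to rescaling any
sample's library size. Constant rows z-score to 0 with a warning.

PAM minimizes total within-cluster dissimilarity over Pearson distances:
greedy BUILD seeding, then best-improvement SWAP to a local optimum (the
cost is asserted non-increasing at every step). Local search can stall in
a shallow local optimum on small problems, so up to a problem size of 60
every point is tried as the BUILD seed and the best local optimum kept —
still deterministic, and in stress tests this attains the
exhaustive-enumeration optimum on all instances with $n \le 8$,
$k \le 3$. Fuzzy membership weights are reciprocal medoid distances
normalized to sum to one (weight 1 on the medoid itself); any monotone
scheme whose argmax equals the hard label would do, and this one is the
simplest. Module counts are configuration, not inference: 6 for gene
modules, 5 for peak–gene co-clusters, 2 for the motif-family subset.
Cluster labels are arbitrary, so all comparisons to planted truth use the
adjusted Rand index. Replicate columns are kept (not averaged) for
clustering, matching per-sample heatmap displays.

## Peak–gene integration

The two assays have unequal replicate counts and possibly unshared
timepoints (the generator drops one ATAC timepoint by default), so
profiles are reduced to per-timepoint means of quantile-normalized log2
CPM on the shared timepoints — the minimal alignment consistent with both
designs — and the choice is recorded in the pair object. Correlation is
computed on these normalized profiles; since Pearson r is invariant to
row-affine transforms, the final z-scoring stage is immaterial here.
Classification is strict: positive iff $r > 0.5$, negative iff
$r < -0.5$; a pair at exactly 0.5, with fewer than 3 shared timepoints,
or with a zero-variance profile stays unclassified. Positive pairs are
re-clustered on the concatenation of their z-scored accessibility and
expression profiles.

## Motifs and enrichment

PWMs carry a pseudocount of 0.01 (avoiding $-\infty$ log-odds), uniform
background, and a default hit threshold of 60% of the motif's maximal
log2-odds score — per-motif calibrated thresholds would need score
distributions we do not model. Windows are scanned on both strands;
ambiguous bases disqualify a window position; overlapping same-motif
same-strand hits within 1 bp collapse to the best; a motif
indistinguishable from background (maximal score ≤ 0) reports no hits.
Offsets are motif-midpoint minus window center, so planted and scanned
offsets are directly comparable.

Enrichment is a one-sided hypergeometric test on the peak-level (or
gene-level, for promoters) hit indicator, foreground versus the remaining
universe; the background is the non-significant consensus peaks rather
than GC-matched genomic draws, a config-exposed choice. Families pool
member hits as a union indicator. The q-value is defined as the
BH-adjusted p; significance is gated at padj < 0.01 and q < 0.05. The
ORA universe defaults to detected features (those passing independent
filtering) — the conservative conventional background.

For qPCR, technical replicates collapse by mean, ΔCt is target minus
reference per sample, ΔΔCt subtracts the calibrator-group mean, fold
change is $2^{-\Delta\Delta Ct}$, and group statistics run on ΔCt values
(Kruskal–Wallis with midranks and tie correction, then pairwise Dunn z
tests with tie-corrected variance and BH adjustment). Fold changes are
invariant to a constant machine offset on all Ct values.

## The synthetic-data generator

`sim_config()` defaults encode the emulated study: 6 weekly timepoints
(P0–P35), 6–9 RNA replicates per timepoint, RIN ~ U(6.7, 10) (the floor
mirrors a quality-inclusion cutoff) acting on the natural-log mean with
coefficient 0.08 — a modest, realistic quality effect; 2 ATAC replicates
per timepoint with the 4th timepoint dropped, forcing the integration
stage to handle unshared timepoints; 22% of genes assigned one of six
temporal shapes (early/late monotone up and down, two intermittent
pulses) with a 2-log2-unit amplitude (a 4-fold swing); per-feature
dispersions U(0.05, 0.2); half the peaks linked to DE genes with a 62/38
positive/negative sign mixture; peak summits at interval midpoints;
per-replicate peak calls jittered ±50 bp plus 10% irreproducible
single-replicate noise calls; blacklist and naked-DNA control regions
that also appear as reproducible spurious calls (so the filter is
actually exercised); and family-specific motifs (TEA for decreasing
accessibility, MADS for increasing, KLF for intermittent) planted at
N(0, 40 bp) offsets from summits. Library-size ranges are config, not
fixed, since no canonical values exist.

What it does **not** emulate: read-level data (everything starts from
counts and peak calls), fragment-length structure, GC/Tn5 sequence bias
beyond the control peak list, correlated gene–gene co-expression beyond
the planted modules, batch effects, or outlier samples. Passing tests on
this generator therefore demonstrate that the algorithms do what they
claim under the declared generative model — not that real tissue data
would yield any particular peak or gene count, which depends on raw
sequencing data this package never touches.

## Problem sizes

The test suite and acceptance script run at desk scale by choice: 150–600
genes and 150–800 peaks for recovery checks, 2,000 features for the null
calibration, 200 Monte-Carlo replicates for parameter-recovery checks.
These sizes give Monte-Carlo error well inside every asserted band while
keeping a full run in the low minutes.

## Known limitations

- Dispersion moderation uses a single global center; a mean–dispersion
  trend (as fitted by the established DE tools) would be better for data
  with a strong trend.
- The F-reference denominator df treats the moderation prior as exact
  information; it is a calibration device validated by simulation, not a
  derived sampling distribution.
- Motif hit thresholds are a fixed fraction of the maximal score, so
  motif families with very different information content are not scanned
  at matched false-positive rates.
- The ATAC counting path assumes reads-in-peaks counts (or fragment
  midpoints) are available; it does not process alignments.
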
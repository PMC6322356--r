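---
title: "Methods: multivariate marker screening and network-based target ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multivariate marker screening and network-based target ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vkmet)
```

This vignette documents the statistical models, the numerical choices,
and the design decisions behind **vkmet**, in the spirit of the methods
sections of the established omics packages. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The analysis problem

A four-group rodent design — healthy controls, a malignant-ascites
model, and two herb-treated groups (crude kansui and vinegar-processed
kansui) — is profiled by LC-MS in serum and urine. The analysis asks
three questions in sequence:

1. which metabolite features separate model from control rats
   (chemometrics + screening),
2. which biochemical pathways those features implicate (annotation +
   pathway analysis), and
3. which protein targets connect the herb's constituents to those
   metabolites (network pharmacology).

## Preprocessing

**Missing values.** LC-MS alignment leaves missing peaks. The default
`half_min` rule imputes half the feature's observed minimum — the usual
limit-of-detection convention; `zero` and `drop_feature` are provided
for sensitivity analyses. A feature with no observed value at all cannot
be imputed and is dropped with a warning.

**QC filtering.** A pooled QC sample injected periodically measures
technical, not biological, variability. Features whose QC relative
standard deviation exceeds 30% (the common metabolomics acceptance
threshold; tunable) are removed. With fewer than two QC injections the
filter is a warned no-op. The filter is idempotent.

**Pareto scaling.** Each feature is mean-centred and divided by the
square root of its sample standard deviation (n − 1 denominator):
intermediate between centring (dominated by abundant ions) and
unit-variance scaling (inflates noise). The scaled column variance
therefore equals the original feature SD — an identity the test suite
asserts at 1e-9 relative tolerance. Zero-variance features map to
all-zero columns and are flagged rather than erroring, so degenerate
toys and constant features survive. Univariate tests (the marker
screen) run on *raw* intensities; scaling feeds only the multivariate
models. No row (total-intensity) normalization is applied by default,
since nothing in the workflow presumes it.

## PCA

PCA is computed by SVD of the centred matrix. In `"auto"` mode the
component count is chosen by cross-validation: loadings are fitted
without the held-out samples, and each held-out entry is predicted from
the *other* variables of its own row (the leave-one-variable-out
projection, computed in closed form from the loading leverages), so no
entry participates in its own prediction. Components are added while
cross-validated Q² improves by more than 0.01. The naive alternative —
projecting the full held-out row — always improves with more components
and cannot select a rank.

## OPLS-DA

Two-class OPLS-DA follows the NIPALS orthogonal-deflation scheme: the
class vector is encoded 0/1 and centred; each Y-orthogonal component is
estimated from the current weight vector, removed from X, and the
predictive weights re-estimated; one predictive component is fitted
last. Reported statistics:

* `R2X` — fraction of X sum of squares captured by all components;
* `R2Y = 1 − RSS/TSS` on the centred class vector;
* `Q2 = 1 − PRESS/TSS` by 7-fold cross-validation (the SIMCA default
  fold count), with deterministic round-robin fold assignment after a
  seeded shuffle stratified by class. Training folds are re-centred;
  held-out rows are projected through the training orthogonal
  components before scoring.

`n_orth = "auto"` adds orthogonal components while cross-validated Q²
improves by more than 0.01. With `n_orth = 0` the model coincides with
single-component PLS1, which the tests verify against an independently
written NIPALS oracle.

**VIP** is computed on the predictive component only — orthogonal
components explain no Y by construction — so with unit-norm weights
`VIP_j = sqrt(p)·|w_j|` and `mean(VIP²) = 1` exactly (asserted on every
fitted model). Users comparing against SIMCA's "VIP total", which mixes
in orthogonal variation, should expect differences.

**S-plot** reports, per scaled feature, the covariance and the
correlation of the feature with the predictive score; a zero-variance
feature has undefined correlation and is reported as 0 with a flag.

**Permutation validation** keeps X fixed, permutes the labels `n_perm`
times (default 200, the conventional count), refits with the observed
model's `n_orth`, and reports
`p = (#{Q²_perm ≥ Q²_obs} + 1)/(n_perm + 1)`, so the smallest
attainable p is `1/(n_perm + 1)`. All permutations are drawn *before*
any fitting: the fitting path seeds its own fold shuffle, and drawing
permutations lazily would let that internal seeding collapse the
permutation stream — a failure mode we guard with a calibration test
(uniform p under the null).

**Null behaviour of Q².** When features far outnumber samples, the
cross-validated predictions of a label-noise model shrink towards the
class mean, so the null Q² concentrates just *below* zero but with a
substantial positive tail; with 12 samples and 30 features roughly
three-quarters of null replicates give Q² ≤ 0. This is a property of
the PRESS statistic, not an implementation artifact — which is exactly
why the permutation test, not the sign of Q², is the validity
criterion.

## Marker screening

A feature is a marker when `VIP > 1.5` (strict) and the two-sided Welch
t-test on raw intensities gives `p < 0.05` (strict). No
multiple-testing correction is applied to the selection — that is the
workflow's stated rule — but a Benjamini–Hochberg column is emitted for
transparency. Fold change is the raw model/control mean ratio; the tie
at exactly 1 is labelled `down`, fixed purely for determinism.
Treated-group recovery is flagged per marker by Welch tests of treated
vs model (`ns`/`p05`/`p01`).

Two consequences of this double gate are worth knowing. On null data
the VIP and p gates select the *same* chance-correlated features, so
the selected count is far below `α · n_features` but well above the
product of the two marginal rates. And on the raw intensity scale the
Welch test is conservative for log-normal data at n = 6 (true size
≈ 4% at the generator's default noise) and loses power against
up-shifted, variance-inflated markers; the test suite freezes these
measured rates rather than idealized ones.

The heatmap matrix z-scores each marker across samples and clusters
both axes with average-linkage hierarchical clustering on Euclidean
distance (Heml-like defaults; the choice is not prescribed anywhere),
with deterministic leaf orders.

## Annotation

Monoisotopic masses are summed from the elemental composition over
C (12 exactly), H (1.0078250319), N (14.0030740052), O (15.9949146221),
P (30.97376151) and S (31.97207069). The charge carrier is the proton
(1.00727646 Da) — not a hydrogen atom — which handles the electron mass
implicitly; formic acid is CH₂O₂ at 46.0054793 Da. Three adducts are
built in (`M+H` positive; `M−H`, `M+FA−H` negative), matching the forms
observed in the bundled metabolite table. Matching is polarity-aware
with a 10 ppm default tolerance applied to the *absolute* signed error;
the gate includes a pair exactly at tolerance and excludes anything
beyond. Isomeric candidates (e.g. the two LysoPC(18:1) forms) are
returned as co-equal rows, never collapsed.

The published mass errors in the bundled metabolite table cannot be
reproduced from its own formulas and adducts (recomputation yields
systematic ~20 ppm offsets, e.g. for cholic acid), so those printed ppm
values are carried as data but never asserted; annotation tests use
self-consistency round trips instead.

## Pathway analysis

Over-representation is the upper-tail hypergeometric probability of the
observed hit count, with the universe defined as the annotated
screening universe (configurable), not all known compounds. The
topology **impact** of a pathway is the share of its relative
betweenness-centrality mass carried by the matched members — 1 when the
matched nodes carry all shortest-path traffic, 0 when they are
peripheral. Pathways whose graph has no betweenness at all (edgeless or
fully symmetric) fall back to uniform centrality `1/|members|`, keeping
the statistic defined and its bounds and monotonicity intact. Raw
p-values are reported (with a BH column) because the workflow ranks on
raw results. Reproducing any specific published impact number would
require the exact curated pathway graphs of the original web tool,
which are deliberately out of scope; the statistic itself is fully
implemented over user-supplied GMT membership and edge lists.

## Network pharmacology

Compounds pass the ADME gate at `OB ≥ 30%` and `DL ≥ 0.18`, with a
whitelist for constituents known to be active despite weak ADME scores;
rule-passing and whitelisted membership are reported separately because
they overlap (on the bundled compound table, one compound satisfies
both, which is why 8 rule-passers plus 13 whitelisted ids yield 20
unique actives).

Three layers — compound–target (bipartite), seed proteins expanded one
hop into a PPI, and gene–metabolite associations — are merged by node
identity (gene symbols are upper-cased first). Protein nodes may
legitimately carry different tags in different layers; the most
specific wins (`target` over `pathway_gene` over `adjacent_protein`),
while a protein/compound or protein/metabolite identity clash is an
error. The candidate targets are the intersection of the
compound-target layer's targets with the protein nodes of the other
two layers.

Centralities are computed on the unweighted, undirected graph:
per-node average shortest path length within the node's connected
component (cross-component pairs are never averaged in), and
betweenness normalized by `(n − 1)(n − 2)/2` within each component.
Isolated nodes have no defined path length and are excluded with a
warning.

The rank score combines min-max-normalized path length with
min-max-normalized *reciprocal* betweenness, each weighted 50%; lower R
is more central. The reciprocal reading is the only one under which the
most-connected candidate scores exactly 0 while staying in [0, 1], and
it makes R invariant to affine rescaling of all path lengths and scalar
rescaling of all betweenness values. Candidates with zero betweenness
(undefined reciprocal) are excluded with a warning; if all path lengths
coincide, that term is zero for everyone, flagged rather than 0/0. Ties
in R are broken lexicographically by node id for determinism. When the
score is recomputed from a table rounded to two decimals in A and five
in B, the induced uncertainty in R is below ±0.005, which is the
agreement budget used against published values.

## The synthetic-data generator

`simulate_feature_study()` emulates the study design: four groups of
`n_per_group = 6`, `n_features = 300` log-normal features (log-mean
drawn per feature and shared across groups), `n_markers = 20` planted
markers shifted by ±`log_fold_change = 1.1` natural-log units in the
model group, and treated groups placed a fraction `recovery` of the way
back towards control. `recovery` defaults to 0.8: the study reports a
strong but not total normalization of the disturbed metabolites in
treated animals, and both treated groups share the parameter because
the processed and crude herb behaved near-identically. Noise is
log-scale Gaussian with `noise_sd = 0.4` (≈ 40% biological CV). Pooled
QC injections sit at the average of the group means with technical
noise `noise_sd/4` (≈ 10% RSD) — a pooled QC mixes all samples, so its
variability is instrumental, not biological.

The baseline log-abundance spread (`baseline_log_sd = 0.3`) is
deliberately narrow. Under Pareto scaling a feature's VIP scales like
the square root of its abundance, so with a decades-wide abundance
range identical planted log effects would produce wildly different VIP
values and the screening rule would be testing abundance, not effect.
The generator favours testability of the statistics over the full
dynamic range of real LC-MS data; the parameter is exposed for users
who want the harder regime. Also not emulated: chromatographic peak
shapes, retention-time drift, isotope patterns, and correlated
metabolite modules — features arrive already aligned and independent.
Consequently, passing tests demonstrate the statistics are computed
correctly and are calibrated under the stated generative model; they
do not certify performance on real spectra.

`simulate_interactome()` builds two random connected communities joined
*only* through one bridge node wired to both sides. The bridge is a cut
vertex: it carries every inter-community shortest path, so it has
maximal betweenness and low average path length by construction, giving
the target-ranking stage a known right answer.

## Problem sizes and runtime choices

The test suite and acceptance checks use the study-scale defaults
(n = 6/group, 300 features) for recovery and calibration runs, 10–20
seeds per Monte-Carlo property, 40–100 replicates for null-distribution
checks, permutation counts of 49–99 inside tests (200 is the analysis
default), and exhaustive graph oracles up to 12 nodes — sizes at which
every derived quantity was actually recomputed while freezing the
expected values.

## Known limitations

* Two-class OPLS-DA only; the four-group view is handled by PCA.
* No MS/MS fragment matching or retention-time modelling in
  annotation; exact mass + adduct only.
* Pathway impact depends entirely on the user-supplied pathway graphs;
  bundled analyses fall back to uniform centrality when no edges are
  given.
* The published network counts that depend on live databases (gene
  universes, PPI sizes) are not reproducible by design; file-based
  ingestion replaces all web services.
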
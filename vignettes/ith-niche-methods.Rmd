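---
title: "Quantifying spatial intratumoural heterogeneity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial intratumoural heterogeneity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ithniche)
```

# The measurement model

`ithniche` analyses intratumoural heterogeneity (ITH) on a virtual lattice of
1 mm² squares overlaid on aligned adjacent immunohistochemistry sections of a
tumour. Every analysable square carries a single positivity value in percent:

* **PNC** (positive nuclear count), `100 · positive nuclei / all nuclei`,
  used for nuclear markers (HIF-1α, HIF-2α, Ki-67). Nuclei are assigned to
  squares by centroid — the simplest unambiguous rule for nuclei straddling a
  square boundary. A square containing no nuclei is flagged and excluded
  rather than scored 0.
* **PPC** (positive pixel count), `100 · positive pixels / cancerous-area
  pixels`, used for cytoplasmic phospho-markers (phospho-mTOR,
  phospho-S6RP). The denominator is the **corrected area**: when part of a
  square is non-cancerous, only the cancerous pixels count, so the score is
  invariant to how much excluded tissue the square happens to contain.

Squares that are entirely non-cancerous are excluded; squares whose tumour
fraction falls below a configurable floor (default 0.05) are also treated as
non-tumour, because a tiny denominator would make the percentage unstable.
This floor is a package decision — no minimum analysable fraction is part of
the original measurement design.

Lattices of one tumour must be aligned: all marker grids share dimensions
and square statuses, and every cross-marker operation enforces that contract
rather than attempting registration. HIF markers span 0–100 %PN; Ki-67 and
the PPC markers saturate around 25%, which is why their heat-map colour
ramps and binning ranges differ.

# Heterogeneity scores and classification

For the per-square values \(x_1,\dots,x_n\) of one tumour and marker, four
scores are computed:

* the sample standard deviation (\(n-1\) denominator);
* **MAX–μ** \(= \max_i x_i - \bar x\), an outlier-sensitivity score. Whether
  the subtracted average should run over *all* squares or only *positive*
  squares is ambiguous in the original description; the package uses the
  mean over all analysed squares, which is well defined for markers where
  every square is positive to some degree. This choice is flagged here for
  review rather than hidden.
* the **Shannon index** \(H=-\sum_i p_i\ln p_i\) and the **inverse Simpson
  index** \(D = 1/\sum_i p_i^2\) over binned data categories.

Binning uses half-open intervals \([kw,(k+1)w)\) with the last bin closed.
Full-range markers use 5% bins over 0–100 (20 categories). Low-range
markers use 2% bins; the original scheme is internally inconsistent (a 0–25%
range at 2% gives 13 categories, yet the category maximum is stated as
s = 20), so the default range for 2% bins is 0–40, which restores s = 20
while comfortably containing the 0–25% data. Both range and width are
arguments, so either reading can be reproduced exactly.

The inverse Simpson index uses the plug-in form \(1/\sum p_i^2\); the
bias-corrected estimator \(1/[\sum n_i(n_i-1)/(N(N-1))]\) is available via
`bias_corrected = TRUE`. Shannon uses the natural logarithm by default (the
conventional ecological form); the base is an argument.

A sample is classified **heterogeneous** when its value histogram departs
from a Gaussian at p < 0.05 under the D'Agostino–Pearson omnibus test. The
statistic \(K^2 = Z(\sqrt{b_1})^2 + Z(b_2)^2\) combines the D'Agostino
(1970) skewness transform with the Anscombe–Glynn (1983) kurtosis transform
and is referred to \(\chi^2_2\). No R package in common use provides this
omnibus test, so it is implemented here from the published transforms; its
values were verified during development against an independent
implementation of the same formulas to 10 decimal places, and its type-I
error at n = 150 is close to nominal (about 5.2% over 50 000 null
samples). The transforms degrade below n = 20 (a warning is issued) and a
hard floor of n = 8 is enforced. Samples passing normality are labelled
not-heterogeneous; no intermediate class exists.

Subgroup comparisons of per-tumour summaries use the Kruskal–Wallis test
for the three prognostic subgroups and a two-sided Mann–Whitney U test when
exactly two groups are compared. No multiple-testing correction is applied
to these scores by default, matching the primary analysis; a
Benjamini–Hochberg option exists for the correlation table.

# Peripheral and central niches

The **peripheral zone** is the set of outermost tumour squares: squares
8-adjacent to the exterior background or on the lattice edge. The exterior
background is found by flood fill over non-tumour squares from the lattice
border, so internal holes (vessels, necrosis) never create periphery.
Background flood fill uses the complementary 4-connectivity when the tumour
adjacency is 8-connected, the standard pairing that keeps diagonal
background channels from tunnelling into holes; 4-connected tumour adjacency
is available by argument. Successive peeling assigns each square a layer
depth; lesions with fewer than three layers have no central zone by
definition and are excluded (`analysable = FALSE`).

Peak-expression localisation asks, per tumour and marker, whether the
highest-valued square lies peripherally. Enrichment over a cohort is tested
with a **one-sided binomial (Bernoulli) tail** \(P[X \ge k \mid n, p]\) at
p = 0.51, the cohort-wide peripheral share when peripheral and central
square totals are nearly balanced. The one-sided direction is a package
decision (the question is specifically peripheral localisation); ties —
maxima in both zones — are counted as central-peaked, conservative against
the peripheral hypothesis, and reported via a tie flag.

# Marker correlation

Markers are correlated across directly corresponding squares of the aligned
sections, with listwise deletion of squares missing in any marker. Spearman
rank correlation with average-rank ties is used, pooled over all squares of
all tumours of a subgroup by default; whether to pool or to average
per-tumour coefficients is not determined by the source analysis, so both
are implemented and pooling is the default. Degrees of correlation follow
the printed scheme on the magnitude — 0.0–0.2 none, 0.2–0.4 weak, 0.4–0.7
moderate-to-good, 0.7–1.0 good-to-very-good — with boundary values assigned
to the upper class (the printed ranges overlap) and the sign reported
separately, since the scheme is applied to negative coefficients too.

# Region-stratified mutational spectra

For each patient with matched central and peripheral exomes, variants
(identity `chrom:pos:ref:alt`; genotype and depth ignored; positions
1-based as in VCF) are stratified into central-only, peripheral-only and
shared sets. The filter cascade is:

1. **Recurrence/dbSNP** (cohort-wide, before any per-patient spectra):
   variants present in ≥ 6 of 8 patients, in either region, are removed, as
   are known variants flagged in dbSNP without clinical context. The flag is
   consumed from an annotation column; no dbSNP build is queried.
2. **Functional class**: SNVs are kept when nonsynonymous, splice-site, or
   stop gain/loss; indels are carried through with their own class labels
   for the region-specific tabulation but never enter the SNV-defined
   spectra.
3. **Strand bias**, per 96-category: a category is declared biased when a
   two-sided binomial test of its pooled forward/reverse supporting reads
   rejects at α = 0.01, and SNVs in a biased category with fewer than two
   reads on the anti-bias strand are removed. The *removal* rule is the
   published one; the *declaration* rule (binomial test, α = 0.01) is a
   package decision, because the original criterion is unstated. This is
   also why the printed patient-pairwise similarity values could only be
   reproduced exactly with the controlled-access data and the original
   rule.

SNVs are classified into 96 categories by their flanking bases and
substitution, collapsed to the pyrimidine strand. Spectra are corrected for
the triplet composition of the target regions: each category's count is
divided by the background count of its context — counted as every 3-mer of
the reference whose centre lies in a target interval, pooled with its
reverse complement into 32 pyrimidine-centred classes stored across a
64-slot table with mirrored slots equal — and rescaled to sum to 1.
Spectra are compared by cosine similarity, per patient (both strata of a
patient pooled) and per stratum (all patients' central vs all peripheral
SNVs merged). An empty stratum after filtering is reported as missing, not
as a zero spectrum.

# What the synthetic generators emulate

The grid generator reproduces the *measurement structure* of the study:
about 75 analysable 1 mm² squares per section (an elongated ellipse in a
6 × 16 lattice with 22% non-tumour squares, at least three tumour layers),
30 tumours in subgroups of 9/10/11, five aligned markers with PNC markers
on a 0–100 scale and low-range markers on 0–25. Its spatial ground truth is
deliberately minimal: a single outermost-layer step of height
`peripheral_delta` over `baseline` (deeper gradients are out of scope),
plus Gaussian noise truncated to the value range. Marker defaults place the
step at twice the noise s.d. — the recoverable enrichment the zone analysis
is designed to detect — and the default geometry keeps the cohort's
peripheral:central square totals near the balanced ratio that motivates the
0.51 Bernoulli success probability. Noise between markers shares a common
per-square Gaussian factor (`rank_correlation`), inducing the positive
cross-marker rank correlations the correlation module recovers.

What it does **not** emulate: real staining chemistry and colour, nuclear
segmentation error, section-to-section registration error, irregular
necrotic geometry, or non-Gaussian (e.g. zero-inflated) positivity
distributions. Passing tests therefore demonstrate that the *analysis
framework* recovers known structure from data of the declared form, not
that any particular biological effect exists in real slides. The slide
rasterizer constructs counts first and writes the grid value from them, so
grid → image → quantification is exact by construction — that round trip
validates the bookkeeping of the counting algorithms, not a segmentation
method.

The variant generator emits a single synthetic contig (default 60 kb) with
a BED covering its whole length, so the "exome background" is well defined
without a genome download; SNV contexts are drawn position-by-position from
pools matching each category's context, making the expected aggregate
spectrum equal the configured signature. Region-private counts default to
the study's central-heavy imbalance (9 central vs 3 peripheral private
variants per patient; a tenth of privates are 1-bp indels). Strand-bias
artifacts are planted as *additional* variants concentrated in designated
low-probability categories with < 2 reads on one strand — planting them as
extra records rather than corrupting true privates keeps "artifacts
removed" and "true variants retained" measurable as separate rates.
Recurrent artifacts are planted identically in ≥ 6 patients. Seeds are
explicit arguments everywhere and the generators restore the global RNG
state.

# Numerical choices and degenerate inputs

* Percent values are clipped to `[0, value_range_max]` after noise;
  documented as truncation, chosen over beta noise as the simplest model
  consistent with percent scales.
* Binning assigns values exactly at a bin boundary to the upper bin, and
  out-of-range values to the last bin with a warning.
* `sd_score` requires ≥ 2 values, `max_mu_score` ≥ 1 (a single value gives
  0), diversity indices require a positive total, and the normality test
  fails loudly on zero variance.
* A constant marker column makes its Spearman coefficients undefined
  (`NA`), not 0.
* Ambiguous bases in an SNV's context exclude the record with a warning;
  a reference mismatch is an error.
* A zero triplet background under a category with counts is an error, so a
  degenerate reference (e.g. poly-A) fails loudly rather than silently
  producing an empty spectrum.

# Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate everything from seeds:
30-tumour cohorts for the cohort analyses; 200 cohorts of 12 tumours for
the zonal power/calibration properties; 2 000 standard-normal samples of
n = 150 for the normality-test calibration; 20 simulated eight-patient
variant sets for spectrum recovery (with a further 10 two-signature sets
for the similarity ordering); and 2 000-square copula pairs for correlation
recovery. These sizes give the property checks stable sampling error while
keeping a full run inexpensive on a single CPU.

# Known limitations

* The colour-deconvolution path for real RGB stains is deliberately out of
  scope; the package consumes label images or precomputed grids.
* No survival analysis, no signature decomposition (NMF), no indel-context
  spectra, and no geodesic distance-to-boundary gradients.
* The strand-bias declaration rule and the one-/two-sidedness of the
  original Bernoulli trial are package decisions where the source is
  silent; both are parameterised.
* The heterogeneity classification depends on sample size through the power
  of the omnibus test: cohorts with fewer squares per section will flag
  fewer samples at the same underlying non-normality.
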
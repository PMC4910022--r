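# ithniche

Spatial intratumoural heterogeneity (ITH) analysis for tile-grid
immunohistochemistry and region-stratified somatic variant sets.

Clear cell renal cell carcinoma — like many solid tumours — shows marked
variation in proliferation and signalling activity between regions of a
single lesion. This package implements a complete, tested pipeline for
asking where that variation sits and how big it is: it quantifies marker
positivity on a virtual grid of 1 mm² squares laid over aligned tumour
sections, scores heterogeneity per tumour and marker, partitions the tumour
lattice into peripheral and central niches and tests whether peak expression
concentrates in the periphery, correlates markers across corresponding
squares, and compares centre- versus periphery-specific mutational spectra.
It is aimed at digital-pathology and cancer-genomics analysts who have
per-square positivity grids (or label images) and annotated variant calls,
and at methodologists who want the full analysis reproducible on synthetic
data with known ground truth.

## What it computes

For each tumour section and marker, positivity per square is either
% positive nuclei (PNC) or % positive pixels (PPC), the latter normalised to
the *corrected area* (the cancerous fraction of the square). Heterogeneity
per sample is summarised by:

- the standard deviation of per-square positivity;
- the MAX–μ score, `max(x) − mean(x)`;
- the Shannon index `H = −Σ p_i ln p_i` and inverse Simpson index
  `D = 1 / Σ p_i²` over binned positivity categories (5% bins over 0–100
  for full-range markers, 2% bins for low-range markers; s = 20 categories
  either way);
- the D'Agostino–Pearson omnibus statistic
  `K² = Z(√b₁)² + Z(b₂)² ~ χ²(2)`; samples with p < 0.05 are classified
  heterogeneous.

The peripheral zone is the outermost layer of tumour squares (exterior flood
fill, so internal holes create no periphery); lesions with fewer than three
layers have no central zone and are excluded. Peripheral enrichment of
peak-expression squares is tested with the one-sided binomial tail
`P[X ≥ k | n, p = 0.51]`. Marker co-expression uses Spearman correlation
over directly corresponding squares with the standard degree labels (0.2 /
0.4 / 0.7 cut-offs). Variant sets from matched central/peripheral exomes are
stratified by region, filtered (recurrence in ≥ 6 of 8 patients, dbSNP
flags, functional class, per-category strand bias), classified into the 96
trinucleotide categories, corrected for the target-region triplet
background, and compared by cosine similarity per patient and per stratum.

Synthetic generators (`simulate_cohort()`, `simulate_slide_image()`,
`simulate_variant_tables()`) produce grids, slide-like label images and
VCF/FASTA/BED variant sets with known ground truth, so every stage is
testable without access to clinical data.

## Worked example

```r
library(ithniche)

cfg <- grid_sim_config(baseline = 4, peripheral_delta = 3, noise_sd = 1.5,
                       value_range_max = 25, seed = 42)
sim <- simulate_marker_grid(cfg, mode = "PNC", marker = "KI67")
sim$grid
#> <marker_grid> KI67 [PNC], 6 x 16 squares, 76 tumour/mixed
#>   value range 0.00-9.27%, 76 analysable squares

heterogeneity_report(sim$grid)
#>   marker n_squares mean   sd max_mu shannon inv_simpson n_categories_s   k2
#> 1   KI67        76 5.63 2.24   3.64    1.46        3.83             20 4.15
#>   p_norm heterogeneous
#> 1  0.126         FALSE

part <- peripheral_mask(sim$grid)
part
#> <zone_partition> 40 peripheral, 36 central squares; depth 3 (analysable)
peak_zone(sim$grid, part)
#> [1] "peripheral"

bernoulli_peak_test(11, 12)$p.value
#> [1] 0.003873391
```

Reading: this simulated Ki-67 section has 76 analysable squares averaging
5.6% positive nuclei with s.d. 2.2; its histogram does not depart from a
Gaussian (p = 0.13), so the sample is not flagged heterogeneous, but its
peak-expression square lies in the 40-square peripheral zone. If 11 of 12
such tumours peaked peripherally, the 0.51-Bernoulli trial would call the
enrichment significant (p ≈ 0.004, `**`).

The numbered scripts under `analysis/` run the full workflow — cohort
simulation, heterogeneity scoring and subgroup comparison, zone analysis,
marker correlation, mutational spectra — and write their tables under
`results/`.

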
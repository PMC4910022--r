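test_that("sd and MAX-mu scores match closed forms and reject degenerate input", {
  expect_equal(sd_score(c(10, 10, 10)), 0)
  expect_equal(sd_score(c(0, 10)), sqrt(50))
  expect_error(sd_score(5), "two values")

  expect_equal(max_mu_score(c(5, 5, 5)), 0)
  expect_equal(max_mu_score(c(0, 0, 10)), 10 - 10 / 3)
  expect_equal(max_mu_score(7), 0)          # single value: max equals mean
  expect_error(max_mu_score(numeric(0)), "one value")
})

test_that("binning uses half-open intervals with a closed last bin", {
  expect_length(bin_values(numeric(0), 100, 5), 20)
  counts <- bin_values(c(0, 4.9, 5.0), 100, 5)
  expect_identical(unname(counts[1:2]), c(2L, 1L))
  expect_identical(sum(counts), 3L)
  # top boundary closed
  expect_identical(unname(bin_values(100, 100, 5)[20]), 1L)
  # out-of-range values go to the last bin with a warning
  expect_warning(counts2 <- bin_values(c(3, 105), 100, 5), "last bin")
  expect_identical(unname(counts2[20]), 1L)
  expect_error(bin_values(1:3, 100, 0), "bin_width")
  # the study schemes both define 20 categories
  expect_length(bin_values(numeric(0), 40, 2), 20)
  spec <- auto_bin_spec(25)
  expect_identical(ceiling(spec$range_max / spec$bin_width), 20)
})

test_that("diversity indices match analytic values and brute-force summation", {
  expect_equal(shannon_index(c(5, 0, 0)), 0)
  expect_equal(shannon_index(rep(3, 4)), log(4))
  expect_equal(shannon_index(rep(1, 20)), log(20))
  expect_equal(shannon_index(rep(1, 4), base = 2), 2)
  expect_equal(inverse_simpson_index(c(9, 0)), 1)
  expect_equal(inverse_simpson_index(rep(2, 7)), 7)
  expect_equal(inverse_simpson_index(c(2, 1, 1)), 1 / 0.375)
  expect_error(shannon_index(c(0, 0)), "zero")
  expect_error(inverse_simpson_index(numeric(0)), "zero")

  # property: agreement with independent loops on random count vectors,
  # invariance to permutation and to empty categories
  set.seed(42)
  for (i in 1:50) {
    counts <- rpois(sample(2:20, 1), lambda = sample(1:10, 1))
    if (sum(counts) == 0) counts[1] <- 1
    expect_equal(shannon_index(counts), shannon_brute(counts))
    expect_equal(inverse_simpson_index(counts), inv_simpson_brute(counts))
    perm <- sample(counts)
    expect_equal(shannon_index(perm), shannon_index(counts))
    expect_equal(inverse_simpson_index(perm), inverse_simpson_index(counts))
    expect_equal(shannon_index(c(counts, 0)), shannon_index(counts))
    expect_equal(inverse_simpson_index(c(counts, 0)),
                 inverse_simpson_index(counts))
  }
})

test_that("bias-corrected inverse Simpson follows the small-sample form", {
  counts <- c(2, 2)
  expect_equal(inverse_simpson_index(counts), 2)
  expect_equal(inverse_simpson_index(counts, bias_corrected = TRUE),
               1 / (sum(counts * (counts - 1)) / (4 * 3)))
})

test_that("omnibus normality statistic matches the published transforms", {
  # expected values frozen from an independent implementation of the same
  # skewness/kurtosis normalizing transforms (D'Agostino 1970,
  # Anscombe-Glynn 1983)
  x <- c(2.3, 4.1, 1.8, 5.5, 3.3, 2.9, 6.1, 0.7, 3.8, 4.4,
         2.2, 5.0, 3.1, 1.5, 4.8, 3.6, 2.7, 5.9, 0.9, 4.2,
         3.0, 2.4, 6.3, 1.1, 3.9)
  r <- dagostino_pearson(x)
  expect_equal(r$k2, 1.1068473296, tolerance = 1e-9)
  expect_equal(r$p.value, 0.5749779051, tolerance = 1e-9)
  expect_equal(r$z_skew, 0.2678843949, tolerance = 1e-9)
  expect_equal(r$z_kurt, -1.0173914097, tolerance = 1e-9)
  expect_false(r$heterogeneous)

  expect_error(dagostino_pearson(rnorm(5)), "at least 8")
  expect_error(dagostino_pearson(rep(3, 30)), "zero variance")
  expect_warning(dagostino_pearson(seq(0, 10, length.out = 15)),
                 "unreliable")
})

test_that("strong bimodality is classified heterogeneous", {
  set.seed(9)
  x <- c(rnorm(75, 5, 1), rnorm(75, 25, 1))
  r <- dagostino_pearson(x)
  expect_true(r$heterogeneous)
  expect_lt(r$p.value, 1e-6)
})

test_that("heterogeneity report assembles all measures consistently", {
  s <- simulate_marker_grid(grid_sim_config(baseline = 10,
                                            peripheral_delta = 30,
                                            noise_sd = 3, seed = 2))
  rep1 <- heterogeneity_report(s$grid)
  expect_identical(rep1$n_squares, length(grid_values(s$grid)))
  expect_identical(rep1$n_categories_s, 20L)
  expect_identical(rep1$heterogeneous, rep1$p_norm < 0.05)
  expect_equal(rep1$max_mu,
               max(grid_values(s$grid)) - mean(grid_values(s$grid)))
  expect_gte(rep1$inv_simpson, 1)
  expect_lte(rep1$inv_simpson, rep1$n_categories_s)
  # scores are invariant to square ordering (values only enter as a set)
  v <- grid_values(s$grid)
  rep2 <- heterogeneity_report(sample(v), value_range_max = 100)
  expect_equal(rep2$sd, rep1$sd)
  expect_equal(rep2$shannon, rep1$shannon)
  expect_equal(rep2$k2, rep1$k2)
})

test_that("subgroup comparison picks the appropriate rank test", {
  set.seed(31)
  vals <- c(rnorm(10, 10), rnorm(10, 10), rnorm(10, 30))
  grp <- rep(c("pT1M0", "pT1M1", "pT3/4"), each = 10)
  r <- subgroup_compare(vals, grp)
  expect_match(r$method, "Kruskal")
  expect_lt(r$p.value, 0.01)
  r2 <- subgroup_compare(vals[1:20], grp[1:20])
  expect_match(r2$method, "Wilcoxon")
  expect_error(subgroup_compare(vals[1:11], grp[1:11]), ">= 2")
})

test_that("rank tests detect shifts and respect the null", {
  set.seed(77)
  null_p <- replicate(60, {
    v <- rnorm(30)
    subgroup_compare(v, rep(c("a", "b", "c"), each = 10))$p.value
  })
  expect_gte(mean(null_p > 0.05), 0.80)
  power_p <- replicate(40, {
    v <- c(rnorm(10), rnorm(10), rnorm(10, 3))
    subgroup_compare(v, rep(c("a", "b", "c"), each = 10))$p.value
  })
  expect_gte(mean(power_p < 0.05), 0.95)
})
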
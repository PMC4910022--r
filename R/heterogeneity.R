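#' Heterogeneity score: sample standard deviation of square positivity
#'
#' @param values Per-square percent positivity (NAs dropped).
#' @return Sample s.d. (n - 1 denominator), in percent units.
#' @export
sd_score <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stop_ith("sd_score needs at least two values")
  stats::sd(v)
}

#' Heterogeneity score: maximum minus mean (MAX-mu)
#'
#' Highlights outlier squares: the difference between the highest square
#' positivity and the average over all analysed squares.
#'
#' @param values Per-square percent positivity (NAs dropped).
#' @return `max(values) - mean(values)`, always >= 0.
#' @export
max_mu_score <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) stop_ith("max_mu_score needs at least one value")
  max(v) - mean(v)
}

#' Bin square positivity into data categories
#'
#' Bins are half-open `[k*w, (k+1)*w)` with the last bin closed at
#' `range_max`, giving `ceiling(range_max / bin_width)` categories. The study
#' scheme uses 5% bins over 0-100% for full-range markers and 2% bins for
#' low-range markers, both yielding a maximum of s = 20 categories. Values
#' above `range_max` are assigned to the last bin with a warning.
#'
#' @param values Percent positivity values (NAs dropped).
#' @param range_max Upper end of the binning range (> 0).
#' @param bin_width Bin width in percent (> 0).
#' @return Named integer vector of category counts summing to the number of
#'   values.
#' @export
bin_values <- function(values, range_max = 100, bin_width = 5) {
  if (!is_scalar_number(bin_width) || bin_width <= 0) {
    stop_ith("bin_width must be a positive number")
  }
  if (!is_scalar_number(range_max) || range_max <= 0) {
    stop_ith("range_max must be a positive number")
  }
  v <- values[!is.na(values)]
  n_bins <- ceiling(range_max / bin_width)
  if (any(v < 0)) stop_ith("negative positivity values")
  if (any(v > range_max)) {
    warning(sum(v > range_max), " value(s) above range_max assigned to last bin")
  }
  idx <- pmin(floor(v / bin_width), n_bins - 1L) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  lo <- (seq_len(n_bins) - 1L) * bin_width
  names(counts) <- sprintf("[%g,%g%s", lo, pmin(lo + bin_width, range_max),
                           c(rep(")", n_bins - 1L), "]"))
  counts
}

#' Default binning scheme for a marker's value range
#'
#' Full-range markers (scale max > 50) use 5% bins over 0-100; low-range
#' markers use 2% bins over a 0-40 range so that both schemes define the same
#' maximum of 20 data categories.
#'
#' @param value_range_max Marker scale maximum (100 or 25 in the study panel).
#' @return List with `range_max` and `bin_width`.
#' @export
auto_bin_spec <- function(value_range_max) {
  if (value_range_max > 50) list(range_max = 100, bin_width = 5)
  else list(range_max = 40, bin_width = 2)
}

#' Shannon diversity index over data-category counts
#'
#' `H = -sum(p_i * log(p_i))` over occupied categories, with `p_i` the
#' proportion of squares in category i.
#'
#' @param counts Non-negative category counts, total > 0.
#' @param base Logarithm base (natural log by default).
#' @return H, in nats for the default base.
#' @export
shannon_index <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stop_ith("counts must be non-negative")
  n <- sum(counts)
  if (n <= 0) stop_ith("all-zero counts")
  p <- counts[counts > 0] / n
  -sum(p * log(p, base = base))
}

#' Inverse Simpson diversity index over data-category counts
#'
#' Plug-in form `D = 1 / sum(p_i^2)`: an effective number of categories that
#' weights common categories heavily, so rare outlier categories barely move
#' it. The bias-corrected form `1 / (sum(n_i (n_i - 1)) / (N (N - 1)))` is
#' available behind `bias_corrected`.
#'
#' @param counts Non-negative category counts, total > 0.
#' @param bias_corrected Use the small-sample corrected estimator.
#' @return D, between 1 and the number of occupied categories (plug-in form).
#' @export
inverse_simpson_index <- function(counts, bias_corrected = FALSE) {
  if (any(counts < 0)) stop_ith("counts must be non-negative")
  n <- sum(counts)
  if (n <= 0) stop_ith("all-zero counts")
  if (bias_corrected) {
    if (n < 2) stop_ith("bias-corrected form needs a total of at least 2")
    denom <- sum(counts * (counts - 1)) / (n * (n - 1))
    if (denom == 0) return(Inf)
    1 / denom
  } else {
    1 / sum((counts / n)^2)
  }
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino (1970) skewness transform and the Anscombe-Glynn
#' (1983) kurtosis transform into the omnibus statistic
#' `K2 = Z(sqrt(b1))^2 + Z(b2)^2`, referred to a chi-squared distribution
#' with 2 d.f. A sample whose positivity histogram departs from a Gaussian
#' (p < 0.05) is classified as heterogeneous.
#'
#' @param values Numeric sample. The transforms are unreliable below n = 20
#'   (a warning is issued); `n_floor` is a hard failure threshold.
#' @param alpha Significance level for the heterogeneous call.
#' @param n_floor Minimum allowed sample size.
#' @return List: `k2`, `z_skew`, `z_kurt`, `p.value`, `n`, and logical
#'   `heterogeneous` (`p.value < alpha`).
#' @export
dagostino_pearson <- function(values, alpha = 0.05, n_floor = 8L) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < n_floor) {
    stop_ith("dagostino_pearson needs at least ", n_floor,
             " values (got ", n, ")")
  }
  if (n < 20) warning("normality transforms are unreliable below n = 20")
  if (stats::sd(x) == 0) stop_ith("zero variance: normality test undefined")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2
  # skewness: D'Agostino's Z(sqrt(b1))
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  a <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / a + sqrt((y / a)^2 + 1))
  # kurtosis: Anscombe-Glynn's Z(b2)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  aa <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  base <- (1 - 2 / aa) / (1 + xk * sqrt(2 / (aa - 4)))
  z2 <- ((1 - 2 / (9 * aa)) - sign(base) * abs(base)^(1 / 3)) /
    sqrt(2 / (9 * aa))
  k2 <- z1^2 + z2^2
  p <- stats::pchisq(k2, df = 2, lower.tail = FALSE)
  list(k2 = k2, z_skew = z1, z_kurt = z2, p.value = p, n = n,
       heterogeneous = p < alpha)
}

#' Full heterogeneity report for one tumour sample and marker
#'
#' Computes the four heterogeneity measures (s.d., MAX-mu, Shannon, inverse
#' Simpson over binned categories) and the normality-based heterogeneity
#' classification.
#'
#' @param grid A `marker_grid`, or a numeric vector of square values.
#' @param marker Marker label (taken from the grid if omitted).
#' @param range_max,bin_width Binning scheme; defaults via [auto_bin_spec()]
#'   using `value_range_max`.
#' @param value_range_max Marker scale maximum used to pick the default
#'   binning (100 unless the grid's mode/marker indicates a low-range
#'   marker).
#' @param alpha Significance level for the heterogeneous call.
#' @return One-row data frame: marker, n_squares, mean, sd, max_mu, shannon,
#'   inv_simpson, n_categories_s, k2, p_norm, heterogeneous.
#' @export
heterogeneity_report <- function(grid, marker = NULL, range_max = NULL,
                                 bin_width = NULL, value_range_max = NULL,
                                 alpha = 0.05) {
  if (inherits(grid, "marker_grid")) {
    values <- grid_values(grid)
    marker <- marker %||% grid$marker
    if (is.null(value_range_max)) {
      value_range_max <- if (grid$mode == "PPC" ||
                             grid$marker == "KI67") 25 else 100
    }
  } else {
    values <- grid[!is.na(grid)]
    marker <- marker %||% "marker"
    value_range_max <- value_range_max %||% 100
  }
  spec <- auto_bin_spec(value_range_max)
  range_max <- range_max %||% spec$range_max
  bin_width <- bin_width %||% spec$bin_width
  counts <- bin_values(values, range_max, bin_width)
  dp <- dagostino_pearson(values, alpha = alpha)
  data.frame(
    marker = marker, n_squares = length(values),
    mean = mean(values), sd = sd_score(values),
    max_mu = max_mu_score(values),
    shannon = shannon_index(counts),
    inv_simpson = inverse_simpson_index(counts),
    n_categories_s = length(counts),
    k2 = dp$k2, p_norm = dp$p.value, heterogeneous = dp$heterogeneous,
    stringsAsFactors = FALSE
  )
}

#' Compare a per-tumour summary measure between prognostic subgroups
#'
#' Kruskal-Wallis test for three or more subgroups; two-sided Mann-Whitney U
#' for exactly two (as used for histological grade).
#'
#' @param values Per-tumour summary values (one per tumour).
#' @param groups Subgroup labels, same length as `values`.
#' @return List: `statistic`, `p.value`, `method`, and per-group sizes.
#' @export
subgroup_compare <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  sizes <- table(groups)
  if (nlevels(groups) < 2 || any(sizes < 2)) {
    stop_ith("need >= 2 groups with >= 2 tumours each")
  }
  if (nlevels(groups) == 2) {
    ht <- stats::wilcox.test(values ~ groups, exact = FALSE)
  } else {
    ht <- stats::kruskal.test(values, groups)
  }
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       method = ht$method, group_sizes = as.vector(sizes),
       groups = levels(groups))
}
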
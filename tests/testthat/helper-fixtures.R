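# Small in-code fixtures shared across test files.

# Rectangular all-tumour grid with the given value matrix.
block_grid <- function(values, mode = "PNC", marker = "SIM") {
  status <- matrix("tumour", nrow(values), ncol(values))
  marker_grid(values, status, marker = marker, mode = mode)
}

# Uniform-value all-tumour grid.
uniform_grid <- function(nr, nc, value, ...) {
  block_grid(matrix(value, nr, nc), ...)
}

# Variant record row(s) in the layout used by the spectra module.
vrec <- function(patient = "P01", region = "central", pos, ref = "C",
                 alt = "T", is_snv = NULL, fwd = 10L, rev = 10L,
                 fclass = "nonsynonymous", dbsnp = FALSE, chrom = "chrS") {
  n <- max(lengths(list(patient, region, pos, ref, alt, fwd, rev, fclass)))
  is_snv <- if (is.null(is_snv)) nchar(ref) == 1 & nchar(alt) == 1 else is_snv
  data.frame(patient = patient, region = region, chrom = chrom, pos = pos,
             ref = ref, alt = alt, is_snv = is_snv, fwd = fwd, rev = rev,
             fclass = fclass, dbsnp = dbsnp, stringsAsFactors = FALSE)[
               seq_len(n), , drop = FALSE]
}

# Independent brute-force oracles (plain loops, no shared code path).
shannon_brute <- function(counts) {
  n <- sum(counts)
  h <- 0
  for (ci in counts) {
    if (ci > 0) {
      p <- ci / n
      h <- h - p * log(p)
    }
  }
  h
}

inv_simpson_brute <- function(counts) {
  n <- sum(counts)
  acc <- 0
  for (ci in counts) acc <- acc + (ci / n) * (ci / n)
  1 / acc
}

max_mu_brute <- function(values) {
  mx <- -Inf
  s <- 0
  for (v in values) {
    if (v > mx) mx <- v
    s <- s + v
  }
  mx - s / length(values)
}

cosine_brute <- function(u, v) {
  dot <- 0; nu <- 0; nv <- 0
  for (i in seq_along(u)) {
    dot <- dot + u[i] * v[i]
    nu <- nu + u[i]^2
    nv <- nv + v[i]^2
  }
  dot / sqrt(nu * nv)
}
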
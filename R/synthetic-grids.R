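#' Configuration for a synthetic marker grid
#'
#' Describes one simulated tumour section on the virtual 1 mm^2 lattice. The
#' ground-truth spatial structure is a single outermost-layer step: every
#' tumour square has expected positivity `baseline`, plus `peripheral_delta`
#' if it lies in the outermost tumour layer, with additive Gaussian noise of
#' s.d. `noise_sd`, truncated to `[0, value_range_max]`.
#'
#' @param rows,cols Lattice dimensions (>= 1).
#' @param tumour_shape `"ellipse"` (deterministic inscribed ellipse) or
#'   `"blob"` (seeded random connected growth).
#' @param nontumor_fraction Fraction of lattice squares that are non-tumour.
#' @param baseline Baseline percent positivity of tumour squares.
#' @param peripheral_delta Additive percent enrichment of the outermost
#'   tumour layer (may be negative, but not below `-baseline`).
#' @param noise_sd Gaussian noise s.d. in percent units (>= 0).
#' @param value_range_max Upper bound of the positivity scale: 100 for
#'   full-range (PNC-type) markers, 25 for low-range (PPC/Ki-67-type).
#' @param seed Integer seed; identical configs give identical output.
#' @return A `grid_sim_config` list.
#' @export
grid_sim_config <- function(rows = 6L, cols = 16L,
                            tumour_shape = c("ellipse", "blob"),
                            nontumor_fraction = 0.22,
                            baseline = 10, peripheral_delta = 0,
                            noise_sd = 0, value_range_max = 100,
                            seed = 1L) {
  tumour_shape <- match.arg(tumour_shape)
  stopifnot(rows >= 1, cols >= 1,
            nontumor_fraction >= 0, nontumor_fraction < 1,
            baseline >= 0, baseline <= 100,
            noise_sd >= 0, value_range_max > 0)
  if (peripheral_delta < -baseline) {
    stop_ith("peripheral_delta must be >= -baseline")
  }
  if (baseline > value_range_max) {
    stop_ith("baseline must not exceed value_range_max")
  }
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         tumour_shape = tumour_shape,
         nontumor_fraction = nontumor_fraction, baseline = baseline,
         peripheral_delta = peripheral_delta, noise_sd = noise_sd,
         value_range_max = value_range_max, seed = as.integer(seed)),
    class = "grid_sim_config"
  )
}

## Deterministic inscribed ellipse covering ~ (1 - nontumor_fraction) of the
## lattice; centred, aspect ratio follows the lattice.
.ellipse_mask <- function(rows, cols, tumour_fraction) {
  if (tumour_fraction >= 1) return(matrix(TRUE, rows, cols))
  s <- sqrt(4 * tumour_fraction / pi)
  a <- min(rows / 2 * s, rows / 2)
  b <- min(cols / 2 * s, cols / 2)
  cr <- (rows + 1) / 2
  cc <- (cols + 1) / 2
  r <- matrix(seq_len(rows), rows, cols)
  cl <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  ((r - cr) / a)^2 + ((cl - cc) / b)^2 <= 1
}

## Random connected blob grown square by square from the lattice centre.
.blob_mask <- function(rows, cols, target_n) {
  mask <- matrix(FALSE, rows, cols)
  start <- c(ceiling(rows / 2), ceiling(cols / 2))
  mask[start[1], start[2]] <- TRUE
  off <- .offsets(4)
  frontier <- function() {
    cand <- matrix(FALSE, rows, cols)
    idx <- which(mask)
    for (k in seq_len(nrow(off))) {
      r <- ((idx - 1L) %% rows) + 1L + off[k, "dr"]
      cl <- ((idx - 1L) %/% rows) + 1L + off[k, "dc"]
      ok <- r >= 1L & r <= rows & cl >= 1L & cl <= cols
      cand[cbind(r[ok], cl[ok])] <- TRUE
    }
    which(cand & !mask)
  }
  while (sum(mask) < target_n) {
    f <- frontier()
    if (!length(f)) break
    mask[sample(f, 1L)] <- TRUE
  }
  mask
}

.single_component <- function(mask, connectivity = 8) {
  idx <- which(mask)
  if (!length(idx)) return(TRUE)
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  seen[idx[1L]] <- TRUE
  queue <- idx[1L]
  off <- .offsets(connectivity)
  nr <- nrow(mask)
  while (length(queue)) {
    i <- queue[[1L]]; queue <- queue[-1L]
    r <- ((i - 1L) %% nr) + 1L
    cl <- ((i - 1L) %/% nr) + 1L
    rr <- r + off[, "dr"]; cc <- cl + off[, "dc"]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= ncol(mask)
    nb <- (cc[ok] - 1L) * nr + rr[ok]
    nb <- nb[mask[nb] & !seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  sum(seen) == sum(mask)
}

#' Simulate one marker grid with known ground truth
#'
#' @param cfg A [grid_sim_config()].
#' @param mode Quantification mode recorded on the grid (`"PNC"` or `"PPC"`).
#' @param marker Marker name recorded on the grid.
#' @return A `grid_sim` list: `grid` (a [marker_grid()]), and `truth` with
#'   the tumour `mask`, per-square `layers` depth and `noiseless` expected
#'   values.
#' @export
simulate_marker_grid <- function(cfg, mode = "PNC", marker = "SIM") {
  stopifnot(inherits(cfg, "grid_sim_config"))
  with_seed(cfg$seed, {
    tf <- 1 - cfg$nontumor_fraction
    mask <- switch(cfg$tumour_shape,
      ellipse = .ellipse_mask(cfg$rows, cfg$cols, tf),
      blob = .blob_mask(cfg$rows, cfg$cols,
                        max(1L, round(tf * cfg$rows * cfg$cols))))
    if (!any(mask)) stop_ith("impossible geometry: tumour region is empty")
    if (!.single_component(mask)) {
      stop_ith("tumour region is not a single connected component")
    }
    layers <- zone_layers(mask)
    noiseless <- matrix(NA_real_, cfg$rows, cfg$cols)
    noiseless[mask] <- clip(
      cfg$baseline + cfg$peripheral_delta * (layers[mask] == 1L),
      0, cfg$value_range_max)
    value <- noiseless
    if (cfg$noise_sd > 0) {
      value[mask] <- clip(
        noiseless[mask] + stats::rnorm(sum(mask), 0, cfg$noise_sd),
        0, cfg$value_range_max)
    }
    status <- matrix(ifelse(mask, "tumour", "nontumour"),
                     cfg$rows, cfg$cols)
    grid <- marker_grid(value, status, marker = marker, mode = mode)
    structure(list(grid = grid,
                   truth = list(mask = mask, layers = layers,
                                noiseless = noiseless),
                   cfg = cfg),
              class = "grid_sim")
  })
}

#' Default five-marker panel specification
#'
#' The study panel: HIF-1a and HIF-2a scored by positive nuclear count on the
#' full 0-100% scale; Ki-67 by nuclear count and phospho-mTOR /
#' phospho-S6RP by positive pixel count on a 0-25% scale. Each marker's
#' peripheral enrichment defaults to twice its noise s.d., the spatial
#' ground-truth structure the zone analysis is designed to recover.
#'
#' @return Data frame with one row per marker: `marker`, `mode`, `baseline`,
#'   `peripheral_delta`, `noise_sd`, `value_range_max`.
#' @export
default_marker_specs <- function() {
  data.frame(
    marker = c("HIF1A", "HIF2A", "KI67", "PMTOR", "PS6RP"),
    mode = c("PNC", "PNC", "PNC", "PPC", "PPC"),
    baseline = c(25, 25, 4, 8, 8),
    peripheral_delta = c(12, 12, 3, 5, 5),
    noise_sd = c(6, 6, 1.5, 2.5, 2.5),
    value_range_max = c(100, 100, 25, 25, 25),
    stringsAsFactors = FALSE
  )
}

#' Simulate the five aligned marker grids of one tumour
#'
#' All markers share one tumour mask (aligned adjacent sections). Noise is
#' correlated across markers through a shared per-square Gaussian factor:
#' with `rank_correlation = rho`, each marker's noise is
#' `sqrt(rho) * z_common + sqrt(1 - rho) * z_marker`, inducing positive
#' inter-marker rank correlation of the measured values.
#'
#' @param shape_cfg A [grid_sim_config()]; its value fields are ignored, only
#'   the geometry (rows, cols, shape, nontumor_fraction) and seed are used.
#' @param markers Marker specification data frame; see
#'   [default_marker_specs()].
#' @param rank_correlation Shared-noise weight in `[0, 1)`.
#' @param subgroup,tumour_id Labels recorded on the panel.
#' @return List: `panel` (a [tumour_panel()]) and `truth` (mask, layers and
#'   per-marker noiseless matrices).
#' @export
simulate_tumour_panel <- function(shape_cfg, markers = default_marker_specs(),
                                  rank_correlation = 0.5,
                                  subgroup = NA_character_,
                                  tumour_id = "T01") {
  stopifnot(inherits(shape_cfg, "grid_sim_config"),
            rank_correlation >= 0, rank_correlation < 1)
  with_seed(shape_cfg$seed, {
    tf <- 1 - shape_cfg$nontumor_fraction
    mask <- switch(shape_cfg$tumour_shape,
      ellipse = .ellipse_mask(shape_cfg$rows, shape_cfg$cols, tf),
      blob = .blob_mask(shape_cfg$rows, shape_cfg$cols,
                        max(1L, round(tf * shape_cfg$rows * shape_cfg$cols))))
    if (!any(mask)) stop_ith("impossible geometry: tumour region is empty")
    layers <- zone_layers(mask)
    n_t <- sum(mask)
    z0 <- stats::rnorm(n_t)
    status <- matrix(ifelse(mask, "tumour", "nontumour"),
                     shape_cfg$rows, shape_cfg$cols)
    grids <- list()
    noiseless <- list()
    for (i in seq_len(nrow(markers))) {
      m <- markers[i, ]
      mu <- clip(m$baseline + m$peripheral_delta * (layers[mask] == 1L),
                 0, m$value_range_max)
      eps <- sqrt(rank_correlation) * z0 +
        sqrt(1 - rank_correlation) * stats::rnorm(n_t)
      v <- matrix(NA_real_, shape_cfg$rows, shape_cfg$cols)
      v[mask] <- clip(mu + m$noise_sd * eps, 0, m$value_range_max)
      nl <- matrix(NA_real_, shape_cfg$rows, shape_cfg$cols)
      nl[mask] <- mu
      grids[[m$marker]] <- marker_grid(v, status, marker = m$marker,
                                       mode = m$mode)
      noiseless[[m$marker]] <- nl
    }
    list(panel = tumour_panel(grids, subgroup = subgroup,
                              tumour_id = tumour_id),
         truth = list(mask = mask, layers = layers, noiseless = noiseless))
  })
}

#' Simulate a cohort of tumour panels in three prognostic subgroups
#'
#' Defaults emulate the study cohort: 30 tumours (9 pT1M0, 10 pT1M1,
#' 11 pT3/4), each an elongated section of roughly 75 analysable 1 mm^2
#' squares with at least three tumour layers, five aligned markers per
#' tumour.
#'
#' @param n_per_subgroup Named integer vector of tumours per subgroup.
#' @param markers See [default_marker_specs()].
#' @param rows,cols,tumour_shape,nontumor_fraction Geometry passed to
#'   [grid_sim_config()].
#' @param rank_correlation Inter-marker shared-noise weight.
#' @param seed Cohort seed; per-tumour seeds are derived from it.
#' @return List of per-tumour results as returned by
#'   [simulate_tumour_panel()].
#' @export
simulate_cohort <- function(n_per_subgroup = c(pT1M0 = 9L, pT1M1 = 10L,
                                               "pT3/4" = 11L),
                            markers = default_marker_specs(),
                            rows = 6L, cols = 16L,
                            tumour_shape = "ellipse",
                            nontumor_fraction = 0.22,
                            rank_correlation = 0.5, seed = 1L) {
  subgroups <- rep(names(n_per_subgroup), n_per_subgroup)
  out <- vector("list", length(subgroups))
  for (i in seq_along(subgroups)) {
    cfg <- grid_sim_config(rows = rows, cols = cols,
                           tumour_shape = tumour_shape,
                           nontumor_fraction = nontumor_fraction,
                           seed = seed * 10000L + i)
    out[[i]] <- simulate_tumour_panel(cfg, markers,
                                      rank_correlation = rank_correlation,
                                      subgroup = subgroups[i],
                                      tumour_id = sprintf("T%02d", i))
  }
  out
}

#' Rasterize a grid realization into a slide-like label image
#'
#' Builds a pixel-level fixture on which the grid quantification can be
#' exercised end-to-end. Counts are constructed first and the grid value is
#' then set from them, so the per-square positive-nucleus (PNC) or
#' positive-pixel (PPC) fraction of the image equals the returned grid's
#' value exactly.
#'
#' @param cfg A [grid_sim_config()].
#' @param px_per_square Square edge length in pixels (>= 8).
#' @param mode `"PNC"` or `"PPC"`: which count defines the returned grid's
#'   values.
#' @param n_nuclei Nuclei per tumour square (PNC mode); must fit as disjoint
#'   disks inside a square.
#' @return List: `grid` (quantized [marker_grid()]), `tumour_px` (logical
#'   pixel mask), `stain` (logical positive-pixel mask), `nuclei` (data frame
#'   of centroids `x`, `y`, radius and positivity), `px_per_square`, and the
#'   underlying `sim` ground truth.
#' @export
simulate_slide_image <- function(cfg, px_per_square = 16L,
                                 mode = c("PNC", "PPC"), n_nuclei = 20L) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "grid_sim_config"))
  if (px_per_square < 8) stop_ith("px_per_square must be >= 8")
  sim <- simulate_marker_grid(cfg, mode = mode)
  px <- as.integer(px_per_square)
  k <- ceiling(sqrt(n_nuclei))
  spacing <- px / k
  radius <- max(1L, floor(spacing / 2) - 1L)
  if (mode == "PNC" && (n_nuclei > k^2 || spacing < 3)) {
    stop_ith("requested nuclei do not fit as disjoint disks in a square")
  }
  mask <- sim$truth$mask
  nr <- nrow(mask); nc <- ncol(mask)
  tumour_px <- matrix(FALSE, nr * px, nc * px)
  stain <- matrix(FALSE, nr * px, nc * px)
  nuclei <- list()
  value_q <- sim$grid$value
  n_nuc_mat <- matrix(NA_integer_, nr, nc)
  with_seed(cfg$seed + 1L, {
    for (r in seq_len(nr)) for (cl in seq_len(nc)) {
      if (!mask[r, cl]) next
      rows_px <- ((r - 1L) * px + 1L):(r * px)
      cols_px <- ((cl - 1L) * px + 1L):(cl * px)
      tumour_px[rows_px, cols_px] <- TRUE
      v <- sim$grid$value[r, cl]
      if (mode == "PNC") {
        n_pos <- round(v / 100 * n_nuclei)
        value_q[r, cl] <- 100 * n_pos / n_nuclei
        cells <- sample(k^2, n_nuclei)
        pos_cells <- if (n_pos > 0) cells[seq_len(n_pos)] else integer(0)
        cy <- ((cells - 1L) %% k + 0.5) * spacing + (r - 1L) * px
        cx <- ((cells - 1L) %/% k + 0.5) * spacing + (cl - 1L) * px
        nuclei[[length(nuclei) + 1L]] <- data.frame(
          row = r - 1L, col = cl - 1L, x = cx, y = cy, radius = radius,
          positive = cells %in% pos_cells)
        n_nuc_mat[r, cl] <- n_nuclei
        # stain channel still drawn so both algorithms see the same image
        n_pos_px <- round(v / 100 * px^2)
      } else {
        n_pos_px <- round(v / 100 * px^2)
        value_q[r, cl] <- 100 * n_pos_px / px^2
      }
      if (n_pos_px > 0) {
        sq <- matrix(FALSE, px, px)
        sq[sample(px^2, n_pos_px)] <- TRUE
        stain[rows_px, cols_px] <- sq
      }
    }
  })
  grid <- marker_grid(value_q, sim$grid$status, marker = sim$grid$marker,
                      mode = mode,
                      n_nuclei = if (mode == "PNC") n_nuc_mat else NULL)
  nuclei <- if (length(nuclei)) do.call(rbind, nuclei) else
    data.frame(row = integer(0), col = integer(0), x = numeric(0),
               y = numeric(0), radius = numeric(0), positive = logical(0))
  list(grid = grid, tumour_px = tumour_px, stain = stain, nuclei = nuclei,
       px_per_square = px, sim = sim)
}
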
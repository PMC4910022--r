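## Peripheral / central zone machinery.
##
## The peripheral tumour zone is the set of outermost tumour squares: squares
## adjacent (8-connectivity by default) to the exterior background or lying on
## the lattice edge. The exterior background is found by flood fill over
## non-tumour squares starting from the lattice border, so internal holes
## (vessels, necrosis) do NOT create periphery. Successive peeling of the
## outermost layer gives each square a layer depth; lesions with fewer than
## three layers have, by definition, no central zone and are not analysable.

.offsets <- function(connectivity) {
  if (connectivity == 8) {
    cbind(dr = rep(-1:1, 3), dc = rep(-1:1, each = 3))[-5, , drop = FALSE]
  } else {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  }
}

## Flood fill over !mask from the border. Background connectivity is the
## complement of the foreground connectivity (8 -> 4, 4 -> 8) so that
## diagonal background channels do not tunnel into holes.
.exterior_background <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  bg_conn <- if (connectivity == 8) 4 else 8
  off <- .offsets(bg_conn)
  ext <- matrix(FALSE, nr, nc)
  border <- which(
    (row(mask) == 1L | row(mask) == nr | col(mask) == 1L | col(mask) == nc) &
      !mask
  )
  if (!length(border)) return(ext)
  ext[border] <- TRUE
  queue <- border
  while (length(queue)) {
    i <- queue[[1L]]; queue <- queue[-1L]
    r <- ((i - 1L) %% nr) + 1L
    cl <- ((i - 1L) %/% nr) + 1L
    rr <- r + off[, "dr"]; cc <- cl + off[, "dc"]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    nb <- (cc[ok] - 1L) * nr + rr[ok]
    nb <- nb[!mask[nb] & !ext[nb]]
    if (length(nb)) {
      ext[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  ext
}

## Squares of `mask` that touch `exterior` (connectivity) or the lattice edge.
.outermost_layer <- function(mask, exterior, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  off <- .offsets(connectivity)
  touches <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(off))) {
    dr <- off[k, "dr"]; dc <- off[k, "dc"]
    src_r <- seq_len(nr) + dr; src_c <- seq_len(nc) + dc
    ok_r <- src_r >= 1L & src_r <= nr
    ok_c <- src_c >= 1L & src_c <= nc
    sh <- matrix(FALSE, nr, nc)
    sh[ok_r, ok_c] <- exterior[src_r[ok_r], src_c[ok_c], drop = FALSE]
    touches <- touches | sh
  }
  edge <- row(mask) == 1L | row(mask) == nr | col(mask) == 1L | col(mask) == nc
  mask & (touches | edge)
}

#' Layer depth of every tumour square by successive peeling
#'
#' Layer 1 is the peripheral (outermost) layer; peeling it away and
#' recomputing the outermost layer of the remainder yields layer 2, and so on
#' until the tumour is exhausted.
#'
#' @param mask Logical matrix, `TRUE` for tumour squares.
#' @param connectivity 8 (default) or 4; adjacency used between tumour squares
#'   and the exterior background.
#' @return Integer matrix of layer depths (`NA` off tumour).
#' @export
zone_layers <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop_ith("no tumour squares in mask")
  layers <- matrix(NA_integer_, nrow(mask), ncol(mask))
  cur <- mask
  depth <- 0L
  while (any(cur)) {
    depth <- depth + 1L
    ext <- .exterior_background(cur, connectivity)
    layer <- .outermost_layer(cur, ext, connectivity)
    if (!any(layer)) layer <- cur  # fully enclosed remnant: peel it all
    layers[layer] <- depth
    cur <- cur & !layer
  }
  layers
}

#' Partition a tumour lattice into peripheral and central zones
#'
#' @param grid A `marker_grid`, or a logical tumour mask.
#' @param connectivity 8 (default) or 4.
#' @param min_depth_analysable Minimum erosion depth for a lesion to have a
#'   central zone worth analysing; lesions of only two layers are excluded.
#' @return A `zone_partition`: logical `peripheral` and `central` masks, the
#'   layer-depth matrix, `erosion_depth` and the `analysable` flag.
#' @export
peripheral_mask <- function(grid, connectivity = 8,
                            min_depth_analysable = 3L) {
  mask <- if (inherits(grid, "marker_grid")) tumour_mask(grid) else grid
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop_ith("no tumour squares in grid")
  layers <- zone_layers(mask, connectivity)
  depth <- max(layers, na.rm = TRUE)
  peripheral <- !is.na(layers) & layers == 1L
  central <- !is.na(layers) & layers > 1L
  structure(
    list(peripheral = peripheral, central = central, layers = layers,
         erosion_depth = depth,
         analysable = depth >= min_depth_analysable,
         connectivity = connectivity),
    class = "zone_partition"
  )
}

#' @export
print.zone_partition <- function(x, ...) {
  cat(sprintf(
    "<zone_partition> %d peripheral, %d central squares; depth %d (%s)\n",
    sum(x$peripheral), sum(x$central), x$erosion_depth,
    if (x$analysable) "analysable" else "not analysable"))
  invisible(x)
}

#' Locate the zone of the peak-expression square
#'
#' Returns the zone of the square(s) attaining the maximum positivity. If
#' maxima occur in both zones the result is `"tied"`; for enrichment counting
#' the conservative convention is to count tied tumours as central-peaked.
#'
#' @param grid A `marker_grid`.
#' @param partition A `zone_partition` for the same lattice.
#' @return `"peripheral"`, `"central"` or `"tied"`.
#' @export
peak_zone <- function(grid, partition) {
  stopifnot(inherits(grid, "marker_grid"), inherits(partition, "zone_partition"))
  if (!partition$analysable) {
    stop_ith("lesion not analysable (erosion depth < 3: no central zone)")
  }
  v <- grid$value
  v[!(partition$peripheral | partition$central)] <- NA
  if (all(is.na(v))) stop_ith("all square values are missing")
  mx <- max(v, na.rm = TRUE)
  at <- !is.na(v) & v == mx
  in_p <- any(at & partition$peripheral)
  in_c <- any(at & partition$central)
  if (in_p && in_c) "tied" else if (in_p) "peripheral" else "central"
}

#' One-sided Bernoulli-trial test for peripheral peak enrichment
#'
#' Tests whether peak-expression squares localise to the tumour periphery
#' more often than expected by chance, with success probability defaulting to
#' 0.51 — the cohort-wide share of peripheral squares when peripheral and
#' central square totals are nearly balanced.
#'
#' @param n_peripheral_peaks Number of tumours whose peak lies in the
#'   peripheral zone (ties counted as central).
#' @param n_tumours Number of analysable tumours.
#' @param p_success Per-tumour success probability under the null.
#' @return List with the one-sided upper-tail `p.value`
#'   (`P[X >= k | n, p]`), the inputs, and a significance `stars` string
#'   (`"*"` for p < 0.05, `"**"` for p < 0.01).
#' @export
bernoulli_peak_test <- function(n_peripheral_peaks, n_tumours,
                                p_success = 0.51) {
  if (!is_scalar_number(n_peripheral_peaks) || !is_scalar_number(n_tumours) ||
      n_peripheral_peaks < 0 || n_peripheral_peaks > n_tumours ||
      n_tumours < 1 || n_peripheral_peaks != round(n_peripheral_peaks)) {
    stop_ith("need integer counts with 0 <= k <= n, n >= 1")
  }
  if (!is_scalar_number(p_success) || p_success <= 0 || p_success >= 1) {
    stop_ith("p_success must lie strictly between 0 and 1")
  }
  p <- stats::pbinom(n_peripheral_peaks - 1, n_tumours, p_success,
                     lower.tail = FALSE)
  stars <- if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  list(p.value = p, k = n_peripheral_peaks, n = n_tumours,
       p_success = p_success, stars = stars)
}

#' Compare square values between central and peripheral zones
#'
#' Two-sided Mann-Whitney U test, as used to exclude that zonal differences
#' are driven by admixed non-tumour cells (microvessel density, leukocytes).
#'
#' @param values_central,values_peripheral Numeric vectors (>= 2 values each).
#' @return `htest` object from [stats::wilcox.test()].
#' @export
zone_value_compare <- function(values_central, values_peripheral) {
  vc <- values_central[!is.na(values_central)]
  vp <- values_peripheral[!is.na(values_peripheral)]
  if (length(vc) < 2 || length(vp) < 2) {
    stop_ith("each zone needs at least two values")
  }
  stats::wilcox.test(vc, vp, exact = FALSE, correct = TRUE)
}

#' Cohort-wide peripheral and central square totals
#'
#' @param partitions List of `zone_partition` objects (one per tumour).
#' @param require_analysable Fail unless every tumour has a central zone
#'   (the cohort analysis excludes two-layer lesions); set `FALSE` to count
#'   squares of arbitrary lesions.
#' @return List with `n_peripheral`, `n_central`, and the empirical
#'   peripheral share `p_peripheral` usable as `p_success` in
#'   [bernoulli_peak_test()].
#' @export
zone_square_counts <- function(partitions, require_analysable = TRUE) {
  stopifnot(length(partitions) > 0,
            all(vapply(partitions, inherits, TRUE, "zone_partition")))
  if (require_analysable &&
      !all(vapply(partitions, `[[`, TRUE, "analysable"))) {
    stop_ith("all tumours must be analysable (erosion depth >= 3)")
  }
  np <- sum(vapply(partitions, function(p) sum(p$peripheral), 0L))
  nc <- sum(vapply(partitions, function(p) sum(p$central), 0L))
  list(n_peripheral = np, n_central = nc,
       p_peripheral = np / (np + nc))
}

#' Peak-localisation table over a cohort of tumour panels
#'
#' For each marker and prognostic subgroup, counts tumours whose peak
#' expression lies in the peripheral zone (ties counted as central) and tests
#' enrichment with the one-sided Bernoulli trial.
#'
#' @param panels List of `tumour_panel` objects.
#' @param p_success Null success probability (see [bernoulli_peak_test()]).
#' @param connectivity Grid connectivity for the zone partition.
#' @return Data frame: marker, subgroup, n tumours, n peripheral peaks,
#'   percent peripheral, p-value and stars.
#' @export
peak_localization_table <- function(panels, p_success = 0.51,
                                    connectivity = 8) {
  stopifnot(all(vapply(panels, inherits, TRUE, "tumour_panel")))
  rows <- list()
  for (panel in panels) {
    part <- peripheral_mask(panel$grids[[1L]], connectivity)
    if (!part$analysable) next
    for (m in names(panel$grids)) {
      pz <- peak_zone(panel$grids[[m]], part)
      rows[[length(rows) + 1L]] <- data.frame(
        marker = m, subgroup = panel$subgroup,
        peripheral_peak = pz == "peripheral", tied = pz == "tied")
    }
  }
  df <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(split(df, list(df$marker, df$subgroup),
                                     drop = TRUE), function(d) {
    k <- sum(d$peripheral_peak)
    n <- nrow(d)
    bt <- bernoulli_peak_test(k, n, p_success)
    data.frame(marker = d$marker[1], subgroup = d$subgroup[1],
               n_tumours = n, n_peripheral_peaks = k,
               pct_peripheral = 100 * k / n, n_tied = sum(d$tied),
               p.value = bt$p.value, stars = bt$stars)
  }))
  rownames(out) <- NULL
  out
}
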
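#' Overlay the virtual grid on a pixel-level tumour mask
#'
#' Builds the lattice of squares covering the image and derives each square's
#' status from its tumour-pixel coverage: 0 gives `nontumour`, full coverage
#' `tumour`, anything in between `mixed` with `area_fraction` equal to the
#' tumour-pixel fraction ("corrected area"). Partial squares at the right and
#' bottom image edges are assessed over their actual pixels. Squares whose
#' tumour fraction falls below `min_tumour_fraction` are treated as
#' non-tumour to avoid unstable denominators.
#'
#' @param tumour_px Logical pixel matrix, `TRUE` for cancerous tissue.
#' @param square_size_px Square edge length in pixels (>= 1).
#' @param min_tumour_fraction Minimum analysable tumour fraction per square.
#' @param marker,mode Metadata recorded on the returned grid skeleton.
#' @return A `marker_grid` skeleton with all values `NA`; the pixel square
#'   size is kept in attribute `square_size_px`.
#' @export
build_grid <- function(tumour_px, square_size_px, min_tumour_fraction = 0.05,
                       marker = "marker", mode = c("PNC", "PPC")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(tumour_px), is.logical(tumour_px), square_size_px >= 1)
  if (!any(tumour_px)) stop_ith("no tumour area in mask")
  px <- as.integer(square_size_px)
  nr <- ceiling(nrow(tumour_px) / px)
  nc <- ceiling(ncol(tumour_px) / px)
  status <- matrix("nontumour", nr, nc)
  af <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    rows_px <- ((r - 1L) * px + 1L):min(r * px, nrow(tumour_px))
    cols_px <- ((cl - 1L) * px + 1L):min(cl * px, ncol(tumour_px))
    frac <- mean(tumour_px[rows_px, cols_px])
    if (frac >= min_tumour_fraction) {
      af[r, cl] <- frac
      status[r, cl] <- if (frac == 1) "tumour" else "mixed"
    }
  }
  g <- marker_grid(matrix(NA_real_, nr, nc), status, af,
                   marker = marker, mode = mode)
  attr(g, "square_size_px") <- px
  g
}

#' Percent positive nuclei per square (PNC algorithm)
#'
#' Assigns nuclei to squares by centroid and scores each analysable square as
#' `100 * positive / total` nuclei within its cancerous area. Squares with no
#' nuclei get an `NA` value and are flagged, excluding them from downstream
#' statistics.
#'
#' @param grid Skeleton from [build_grid()].
#' @param nuclei Data frame with centroid columns `x`, `y` (pixel
#'   coordinates, x along image columns, y along rows) and logical
#'   `positive`.
#' @param tumour_px Optional pixel mask; nuclei whose centroid falls on
#'   non-cancerous pixels are excluded from the counts.
#' @return The grid with `value` and `n_nuclei` filled in; flagged squares
#'   are listed in attribute `flagged_squares`.
#' @export
positive_nuclear_count <- function(grid, nuclei, tumour_px = NULL) {
  stopifnot(inherits(grid, "marker_grid"))
  px <- attr(grid, "square_size_px")
  if (is.null(px)) stop_ith("grid lacks a pixel square size (use build_grid)")
  keep <- rep(TRUE, nrow(nuclei))
  if (!is.null(tumour_px) && nrow(nuclei)) {
    pr <- clip(ceiling(nuclei$y), 1, nrow(tumour_px))
    pc <- clip(ceiling(nuclei$x), 1, ncol(tumour_px))
    keep <- tumour_px[cbind(pr, pc)]
  }
  nuc <- nuclei[keep, , drop = FALSE]
  sq_r <- pmin(ceiling(nuc$y / px), nrow(grid$value))
  sq_c <- pmin(ceiling(nuc$x / px), ncol(grid$value))
  value <- grid$value
  n_mat <- matrix(NA_integer_, nrow(value), ncol(value))
  flagged <- list()
  analysable <- which(grid$status != "nontumour", arr.ind = TRUE)
  for (i in seq_len(nrow(analysable))) {
    r <- unname(analysable[i, 1]); cl <- unname(analysable[i, 2])
    in_sq <- sq_r == r & sq_c == cl
    n <- sum(in_sq)
    n_mat[r, cl] <- n
    if (n == 0L) {
      value[r, cl] <- NA_real_
      flagged[[length(flagged) + 1L]] <- c(row = r - 1L, col = cl - 1L)
    } else {
      value[r, cl] <- 100 * sum(nuc$positive[in_sq]) / n
    }
  }
  out <- marker_grid(value, grid$status, grid$area_fraction,
                     marker = grid$marker, mode = "PNC", n_nuclei = n_mat)
  attr(out, "square_size_px") <- px
  attr(out, "flagged_squares") <-
    if (length(flagged)) do.call(rbind, flagged) else NULL
  out
}

#' Percent positive pixels per square (PPC algorithm)
#'
#' Scores each analysable square as `100 * positive pixels / cancerous-area
#' pixels`: the denominator of a mixed square is its corrected (cancerous)
#' area, so the score is invariant to how much non-cancerous tissue was
#' excluded.
#'
#' @param grid Skeleton from [build_grid()].
#' @param stain Logical pixel matrix of positively stained pixels.
#' @param tumour_px Logical pixel matrix of cancerous tissue (the mask the
#'   grid was built from).
#' @return The grid with `value` filled in, in PPC mode.
#' @export
positive_pixel_count <- function(grid, stain, tumour_px) {
  stopifnot(inherits(grid, "marker_grid"),
            identical(dim(stain), dim(tumour_px)))
  px <- attr(grid, "square_size_px")
  if (is.null(px)) stop_ith("grid lacks a pixel square size (use build_grid)")
  value <- grid$value
  analysable <- which(grid$status != "nontumour", arr.ind = TRUE)
  for (i in seq_len(nrow(analysable))) {
    r <- analysable[i, 1]; cl <- analysable[i, 2]
    rows_px <- ((r - 1L) * px + 1L):min(r * px, nrow(tumour_px))
    cols_px <- ((cl - 1L) * px + 1L):min(cl * px, ncol(tumour_px))
    tum <- tumour_px[rows_px, cols_px]
    denom <- sum(tum)
    if (denom == 0L) {
      stop_ith("analysable square with zero cancerous pixels: ",
               "status contract violated at (", r - 1L, ",", cl - 1L, ")")
    }
    value[r, cl] <- 100 * sum(stain[rows_px, cols_px] & tum) / denom
  }
  out <- marker_grid(value, grid$status, grid$area_fraction,
                     marker = grid$marker, mode = "PPC")
  attr(out, "square_size_px") <- px
  out
}

#' Quantify a synthetic slide image back into a marker grid
#'
#' Convenience wrapper: [build_grid()] on the slide's tumour mask followed by
#' [positive_nuclear_count()] or [positive_pixel_count()] according to
#' `mode`. On images produced by [simulate_slide_image()] this reproduces the
#' generating grid exactly.
#'
#' @param slide List returned by [simulate_slide_image()].
#' @param mode `"PNC"` or `"PPC"`; defaults to the slide's own mode.
#' @return A `marker_grid`.
#' @export
quantify_slide <- function(slide, mode = NULL) {
  mode <- mode %||% slide$grid$mode
  skel <- build_grid(slide$tumour_px, slide$px_per_square,
                     marker = slide$grid$marker, mode = mode)
  if (mode == "PNC") {
    positive_nuclear_count(skel, slide$nuclei, slide$tumour_px)
  } else {
    positive_pixel_count(skel, slide$stain, slide$tumour_px)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a marker grid as a green-to-red heat map
#'
#' Renders per-square positivity on a green (0) to red (`scale_max`) ramp;
#' completely non-cancerous squares are drawn white. Values above
#' `scale_max` are clipped to red with a warning. The default scale is 100
#' for full-range PNC markers (HIF-1a/HIF-2a) and 25 otherwise (Ki-67 and
#' the PPC markers).
#'
#' @param grid A `marker_grid`.
#' @param png_path Optional path to write a PNG rendering.
#' @param tsv_path Optional path for the TSV mirror of all square values.
#' @param scale_max Upper end of the colour ramp, in percent.
#' @param px Rendered pixels per square.
#' @return Invisibly, the matrix of hex colours.
#' @export
heatmap_export <- function(grid, png_path = NULL, tsv_path = NULL,
                           scale_max = NULL, px = 12L) {
  stopifnot(inherits(grid, "marker_grid"))
  if (is.null(scale_max)) {
    scale_max <- if (grid$mode == "PNC" &&
                     grepl("^HIF", grid$marker)) 100 else 25
  }
  v <- grid$value
  if (any(!is.na(v) & v > scale_max)) {
    warning(sum(!is.na(v) & v > scale_max),
            " square value(s) above scale_max clipped to red")
  }
  ramp <- grDevices::colorRamp(c("#1A9641", "#FFFF66", "#D7191C"))
  cols <- matrix("#FFFFFF", nrow(v), ncol(v))
  idx <- which(!is.na(v))
  if (length(idx)) {
    rgbv <- ramp(clip(v[idx] / scale_max, 0, 1))
    cols[idx] <- grDevices::rgb(rgbv[, 1], rgbv[, 2], rgbv[, 3],
                                maxColorValue = 255)
  }
  if (!is.null(png_path)) {
    arr <- array(0, dim = c(nrow(v) * px, ncol(v) * px, 3))
    rgbm <- grDevices::col2rgb(cols) / 255
    for (ch in 1:3) {
      chm <- matrix(rgbm[ch, ], nrow(v), ncol(v))
      arr[, , ch] <- chm[rep(seq_len(nrow(v)), each = px),
                         rep(seq_len(ncol(v)), each = px)]
    }
    png::writePNG(arr, png_path)
  }
  if (!is.null(tsv_path)) write_grid_tsv(grid, tsv_path)
  invisible(cols)
}
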
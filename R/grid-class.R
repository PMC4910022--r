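#' Marker grid: the virtual 1 mm^2 lattice for one section and one marker
#'
#' A `marker_grid` stores, for every square of the virtual grid overlaid on a
#' stained tumour section, its status (`tumour`, `mixed`, `nontumour`), the
#' fraction of the square that is cancerous ("corrected area"), and the
#' positivity value: percent positive nuclei (PNC mode) or percent positive
#' pixels (PPC mode), always expressed relative to the cancerous area.
#'
#' @param value Numeric matrix of per-square positivity in `[0, 100]`;
#'   `NA` for non-tumour squares (and for tumour squares flagged
#'   unanalysable, e.g. zero nuclei in PNC mode).
#' @param status Character matrix (same dim) with entries
#'   `"tumour"`, `"mixed"` or `"nontumour"`.
#' @param area_fraction Numeric matrix of cancerous-area fractions;
#'   defaults to 1 for tumour squares and 0 for non-tumour squares.
#' @param marker Marker identifier (e.g. `"HIF1A"`, `"KI67"`).
#' @param mode `"PNC"` (positive nuclear count) or `"PPC"` (positive pixel
#'   count).
#' @param n_nuclei Optional integer matrix of nuclei counted per square
#'   (PNC mode).
#' @param square_size Physical edge length of a square in mm (default 1).
#' @return An object of class `marker_grid`.
#' @export
marker_grid <- function(value, status, area_fraction = NULL,
                        marker = "marker", mode = c("PNC", "PPC"),
                        n_nuclei = NULL, square_size = 1) {
  mode <- match.arg(mode)
  if (!is.matrix(value) || !is.matrix(status)) {
    stop_ith("'value' and 'status' must be matrices")
  }
  if (!identical(dim(value), dim(status))) {
    stop_ith("'value' and 'status' must share dimensions")
  }
  if (!all(status %in% c("tumour", "mixed", "nontumour"))) {
    stop_ith("status entries must be 'tumour', 'mixed' or 'nontumour'")
  }
  if (is.null(area_fraction)) {
    area_fraction <- matrix(ifelse(status == "nontumour", 0, 1), nrow(status))
  }
  if (!identical(dim(area_fraction), dim(status))) {
    stop_ith("'area_fraction' must share dimensions with 'status'")
  }
  if (any(!is.na(value) & status == "nontumour")) {
    stop_ith("non-tumour squares must carry NA values")
  }
  if (any(!is.na(value) & (value < 0 | value > 100))) {
    stop_ith("positivity values must lie in [0, 100]")
  }
  mixed <- status == "mixed"
  if (any(mixed & (area_fraction <= 0 | area_fraction >= 1))) {
    stop_ith("mixed squares require 0 < area_fraction < 1")
  }
  structure(
    list(value = value, status = status, area_fraction = area_fraction,
         marker = marker, mode = mode, n_nuclei = n_nuclei,
         square_size = square_size),
    class = "marker_grid"
  )
}

#' @export
print.marker_grid <- function(x, ...) {
  n_t <- sum(x$status != "nontumour")
  cat(sprintf("<marker_grid> %s [%s], %d x %d squares, %d tumour/mixed\n",
              x$marker, x$mode, nrow(x$value), ncol(x$value), n_t))
  v <- grid_values(x)
  if (length(v)) {
    cat(sprintf("  value range %.2f-%.2f%%, %d analysable squares\n",
                min(v), max(v), length(v)))
  }
  invisible(x)
}

#' Logical mask of tumour (incl. mixed) squares
#' @param grid A `marker_grid`.
#' @return Logical matrix, `TRUE` where the square contains tumour.
#' @export
tumour_mask <- function(grid) {
  stopifnot(inherits(grid, "marker_grid"))
  grid$status != "nontumour"
}

#' Non-missing positivity values of the analysable squares
#' @param grid A `marker_grid`.
#' @return Numeric vector of per-square percent positivity.
#' @export
grid_values <- function(grid) {
  stopifnot(inherits(grid, "marker_grid"))
  v <- grid$value[tumour_mask(grid)]
  v[!is.na(v)]
}

#' @export
as.data.frame.marker_grid <- function(x, ...) {
  d <- dim(x$value)
  df <- data.frame(
    row = rep(seq_len(d[1]) - 1L, times = d[2]),
    col = rep(seq_len(d[2]) - 1L, each = d[1]),
    status = as.vector(x$status),
    area_fraction = as.vector(x$area_fraction),
    value = as.vector(x$value)
  )
  if (!is.null(x$n_nuclei)) df$n_nuclei <- as.vector(x$n_nuclei)
  df
}

#' Write a marker grid as TSV (columns row, col, status, area_fraction, value)
#' @param grid A `marker_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid_tsv <- function(grid, path) {
  utils::write.table(as.data.frame(grid), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker grid from TSV
#' @param path TSV produced by [write_grid_tsv()].
#' @inheritParams marker_grid
#' @return A `marker_grid`.
#' @export
read_grid_tsv <- function(path, marker = "marker", mode = c("PNC", "PPC"),
                          square_size = 1) {
  mode <- match.arg(mode)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("row", "col", "status", "area_fraction", "value")
  if (!all(need %in% names(df))) {
    stop_ith("grid TSV must have columns ", paste(need, collapse = ", "))
  }
  nr <- max(df$row) + 1L
  nc <- max(df$col) + 1L
  idx <- cbind(df$row + 1L, df$col + 1L)
  mk <- function(v, init) { m <- matrix(init, nr, nc); m[idx] <- v; m }
  n_nuc <- if ("n_nuclei" %in% names(df)) mk(df$n_nuclei, NA_integer_) else NULL
  marker_grid(mk(df$value, NA_real_), mk(df$status, "nontumour"),
              mk(df$area_fraction, 0), marker = marker, mode = mode,
              n_nuclei = n_nuc, square_size = square_size)
}

#' Bundle the five aligned marker grids of one tumour
#'
#' All grids of a tumour must be measured on aligned adjacent sections and
#' therefore share lattice dimensions and square statuses; this constructor
#' enforces that alignment contract.
#'
#' @param grids Named list of `marker_grid` objects.
#' @param subgroup Prognostic subgroup label, one of `"pT1M0"`, `"pT1M1"`,
#'   `"pT3/4"` (other labels allowed for non-study cohorts).
#' @param tumour_id Identifier for the tumour.
#' @return An object of class `tumour_panel`.
#' @export
tumour_panel <- function(grids, subgroup = NA_character_,
                         tumour_id = NA_character_) {
  if (!length(grids) || !all(vapply(grids, inherits, TRUE, "marker_grid"))) {
    stop_ith("'grids' must be a non-empty list of marker_grid objects")
  }
  ref <- grids[[1L]]
  for (g in grids[-1L]) {
    if (!identical(dim(g$status), dim(ref$status)) ||
        !identical(g$status, ref$status)) {
      stop_ith("aligned marker grids must share lattice dimensions and statuses")
    }
  }
  if (is.null(names(grids))) {
    names(grids) <- vapply(grids, function(g) g$marker, character(1))
  }
  structure(list(grids = grids, subgroup = subgroup, tumour_id = tumour_id),
            class = "tumour_panel")
}

#' @export
print.tumour_panel <- function(x, ...) {
  cat(sprintf("<tumour_panel> %s (%s): markers %s\n",
              x$tumour_id, x$subgroup,
              paste(names(x$grids), collapse = ", ")))
  invisible(x)
}
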
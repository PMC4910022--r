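#' Pair marker values across directly corresponding squares
#'
#' Builds one row per tumour square carrying all marker values of the
#' aligned adjacent sections; squares with a missing value in any marker are
#' dropped listwise.
#'
#' @param panel A [tumour_panel()] (lattice alignment is enforced by the
#'   constructor).
#' @return Data frame: `tumour_id`, `subgroup`, `row`, `col`, and one column
#'   per marker.
#' @export
align_panels <- function(panel) {
  stopifnot(inherits(panel, "tumour_panel"))
  mask <- tumour_mask(panel$grids[[1L]])
  idx <- which(mask, arr.ind = TRUE)
  df <- data.frame(tumour_id = panel$tumour_id, subgroup = panel$subgroup,
                   row = idx[, 1] - 1L, col = idx[, 2] - 1L)
  for (m in names(panel$grids)) df[[m]] <- panel$grids[[m]]$value[idx]
  complete <- stats::complete.cases(df[, names(panel$grids), drop = FALSE])
  df[complete, , drop = FALSE]
}

#' Spearman correlation matrix over pooled squares of a subgroup
#'
#' Pairwise Spearman rank correlation (average-rank tie handling, as in
#' [stats::cor()]) between marker columns, pooled over all squares of all
#' tumours supplied. Constant columns yield `NA` for their pairs.
#'
#' @param rows Data frame from [align_panels()] (possibly row-bound over
#'   tumours), or any data frame whose non-metadata columns are marker
#'   values.
#' @param subgroup Label recorded on the result.
#' @param markers Which columns to correlate; defaults to all columns other
#'   than `tumour_id`, `subgroup`, `row`, `col`.
#' @param min_rows Minimum number of squares required.
#' @return A `correlation_table`: list with the `rho` matrix, `n` squares
#'   used, `subgroup`, and the long-format `table` of pairs with
#'   [degree_label()] annotations.
#' @export
spearman_matrix <- function(rows, subgroup = NA_character_, markers = NULL,
                            min_rows = 10L) {
  meta <- c("tumour_id", "subgroup", "row", "col")
  markers <- markers %||% setdiff(names(rows), meta)
  x <- as.matrix(rows[, markers, drop = FALSE])
  if (nrow(x) < min_rows) {
    stop_ith("need at least ", min_rows, " squares (got ", nrow(x), ")")
  }
  constant <- apply(x, 2, function(v) stats::sd(v) == 0)
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  rho[constant, ] <- NA
  rho[, constant] <- NA
  diag(rho) <- ifelse(constant, NA, 1)
  pairs <- utils::combn(markers, 2)
  tab <- data.frame(
    subgroup = subgroup,
    marker1 = pairs[1, ], marker2 = pairs[2, ],
    rho = rho[t(pairs)], n = nrow(x)
  )
  tab$degree <- vapply(tab$rho, function(r)
    if (is.na(r)) NA_character_ else degree_label(r), character(1))
  tab$sign <- ifelse(is.na(tab$rho), NA_character_,
                     ifelse(tab$rho < 0, "negative", "positive"))
  structure(list(rho = rho, n = nrow(x), subgroup = subgroup, table = tab),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, ...) {
  cat(sprintf("<correlation_table> subgroup %s, n = %d squares\n",
              x$subgroup, x$n))
  print(round(x$rho, 3))
  invisible(x)
}

#' Label the degree of a Spearman correlation
#'
#' Uses the magnitude: 0.0-0.2 none, 0.2-0.4 weak, 0.4-0.7 moderate-to-good,
#' 0.7-1.0 good-to-very-good, with boundary values assigned to the upper
#' class. The sign is reported separately by callers.
#'
#' @param rho Correlation coefficient, `|rho| <= 1`.
#' @return One of `"none"`, `"weak"`, `"moderate-to-good"`,
#'   `"good-to-very-good"`.
#' @export
degree_label <- function(rho) {
  if (!is_scalar_number(rho) || abs(rho) > 1) {
    stop_ith("rho must be a number with |rho| <= 1")
  }
  a <- abs(rho)
  if (a >= 0.7) "good-to-very-good"
  else if (a >= 0.4) "moderate-to-good"
  else if (a >= 0.2) "weak"
  else "none"
}

#' Subgroup-wise marker correlation over a cohort
#'
#' Pools the aligned squares of all tumours in each prognostic subgroup
#' (the default), or averages per-tumour correlation matrices when
#' `pooled = FALSE`.
#'
#' @param panels List of [tumour_panel()] objects.
#' @param pooled Pool squares across tumours (default) or average per-tumour
#'   rho matrices.
#' @param p_adjust Optional multiple-testing adjustment of the pairwise
#'   p-values across all pairs and subgroups (e.g. `"BH"`); `"none"` by
#'   default, matching the primary analysis.
#' @return Long data frame of subgroup x pair x rho x n x degree.
#' @export
cohort_correlation <- function(panels, pooled = TRUE, p_adjust = "none") {
  stopifnot(all(vapply(panels, inherits, TRUE, "tumour_panel")))
  aligned <- do.call(rbind, lapply(panels, align_panels))
  out <- list()
  for (sg in unique(aligned$subgroup)) {
    d <- aligned[aligned$subgroup == sg, , drop = FALSE]
    if (pooled) {
      out[[sg]] <- spearman_matrix(d, subgroup = sg)$table
    } else {
      per <- lapply(split(d, d$tumour_id), function(dt) {
        tryCatch(spearman_matrix(dt, subgroup = sg)$rho, error = function(e) NULL)
      })
      per <- Filter(Negate(is.null), per)
      rho <- Reduce(`+`, per) / length(per)
      pairs <- utils::combn(colnames(rho), 2)
      out[[sg]] <- data.frame(subgroup = sg, marker1 = pairs[1, ],
                              marker2 = pairs[2, ], rho = rho[t(pairs)],
                              n = nrow(d),
                              degree = vapply(rho[t(pairs)], degree_label,
                                              character(1)),
                              sign = ifelse(rho[t(pairs)] < 0, "negative",
                                            "positive"))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (p_adjust != "none") {
    # two-sided large-sample p for each rho, then the requested adjustment
    z <- sqrt(res$n - 3) * atanh(res$rho)
    res$p.value <- 2 * stats::pnorm(-abs(z))
    res$p.adj <- stats::p.adjust(res$p.value, method = p_adjust)
  }
  res
}
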
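#' Heat map of a sample-level grid
#'
#' Draws a [sample_matrix()] result in the layout's spatial arrangement:
#' one cell per tile, rows/columns as on the chip or slide, color scale
#' auto-ranged to the non-missing values. Unused or empty tiles render in
#' the reserved missing-data color.
#'
#' @param object A `sample_grid` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sample_grid
#' @export
autoplot.sample_grid <- function(object, ...) {
  sc <- attr(object, "scale")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$col, y = .data$row,
                                       fill = .data$value)) +
    ggplot2::geom_tile(color = "grey60", linewidth = 0.2) +
    ggplot2::scale_y_reverse(breaks = unique(object$row)) +
    ggplot2::scale_x_continuous(breaks = unique(object$col)) +
    ggplot2::scale_fill_viridis_c(limits = sc, na.value = "grey15") +
    ggplot2::labs(x = "tile column", y = "tile row",
                  fill = attr(object, "metric"),
                  title = paste0("Sample view: ", attr(object, "metric"))) +
    ggplot2::theme_minimal()
}

#' @export
plot.sample_grid <- function(x, ...) print(autoplot.sample_grid(x, ...))

#' Heat map of a stacked or per-tile x-y grid
#'
#' @param grid A tibble with `gx`, `gy`, `value` columns, as returned by
#'   [stack_tiles_xy()] or [spatial_composition_map()] (rename `fraction`
#'   to `value` or pass as-is; the first of `value`/`fraction` found is
#'   used).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_xy_grid <- function(grid, title = "Stacked x-y summary") {
  val <- if ("value" %in% names(grid)) "value" else "fraction"
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$gx, y = .data$gy,
                                     fill = .data[[val]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey15") +
    ggplot2::labs(x = "grid x", y = "grid y", title = title, fill = val) +
    ggplot2::theme_minimal()
}

#' Line plot of per-cycle composition
#'
#' One line per symbol (and per group when the composition was computed at
#' tile-row/column or tile scope), tracing the called-symbol fraction along
#' sequencing cycles.
#'
#' @param comp A [cycle_composition()] tibble.
#' @param symbol Optionally restrict to one symbol (one line per group).
#' @return A ggplot object.
#' @export
plot_cycle_composition <- function(comp, symbol = NULL) {
  if (!is.null(symbol)) {
    comp <- dplyr::filter(comp, .data$symbol == !!symbol)
    ggplot2::ggplot(comp, ggplot2::aes(x = .data$cycle, y = .data$fraction,
                                       color = .data$group)) +
      ggplot2::geom_line() +
      ggplot2::labs(title = paste0("Per-cycle fraction of '", symbol, "'"),
                    x = "cycle", y = "fraction of called symbols") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(comp, ggplot2::aes(x = .data$cycle, y = .data$fraction,
                                       color = .data$symbol,
                                       group = paste(.data$group, .data$symbol))) +
      ggplot2::geom_line() +
      ggplot2::labs(title = "Per-cycle symbol composition",
                    x = "cycle", y = "fraction of called symbols") +
      ggplot2::theme_minimal()
  }
}

#' Line plot of the per-cycle mismatch rate
#'
#' @param rates A [mismatch_rate_per_cycle()] tibble.
#' @return A ggplot object.
#' @export
plot_mismatch_rate <- function(rates) {
  ggplot2::ggplot(rates, ggplot2::aes(x = .data$cycle, y = .data$rate)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(title = "Mismatch rate per cycle (unique hits)",
                  x = "cycle", y = "mismatch rate") +
    ggplot2::theme_minimal()
}

#' Bar chart of a target-hit histogram
#'
#' @param hist A [target_hit_histogram()] tibble.
#' @return A ggplot object.
#' @export
plot_target_histogram <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$bin_start, y = .data$count)) +
    ggplot2::geom_col(width = max(1, hist$bin_end[1] - hist$bin_start[1])) +
    ggplot2::facet_wrap(~reference, ncol = 1, scales = "free_x") +
    ggplot2::labs(title = "Alignment starts along the target",
                  x = "position (bp)", y = "reads") +
    ggplot2::theme_minimal()
}

#' Bar chart of pair-QC categories
#'
#' The library-QC overview: counts of good pairs, the two orphan-end
#' classes, and the three chimera/abnormal-separation classes.
#'
#' @param object A [summarize_pairs()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pair_summary
#' @export
autoplot.pair_summary <- function(object, ...) {
  d <- dplyr::mutate(object$counts,
                     category = factor(.data$category, levels = pair_category_levels))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(title = sprintf("Pair categories (chimera fraction %.1f%%)",
                                  100 * object$chimera_fraction),
                  x = NULL, y = "pairs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
plot.pair_summary <- function(x, ...) print(autoplot.pair_summary(x, ...))

#' Strand-split pair-distance distribution
#'
#' Signed distances (start of end 1 minus start of end 2) of good pairs,
#' drawn separately for first ends on the plus and minus strand so strand
#' bias in the library is visible.
#'
#' @param ps A [summarize_pairs()] result.
#' @return A ggplot object.
#' @export
plot_pair_distances <- function(ps) {
  ggplot2::ggplot(ps$distances,
                  ggplot2::aes(x = .data$bin_start, y = .data$n,
                               fill = .data$strand)) +
    ggplot2::geom_col(position = "identity", alpha = 0.6, width = ps$hist_bin) +
    ggplot2::labs(title = "Good-pair signed distance by first-end strand",
                  x = "start1 - start2 (bp)", y = "pairs") +
    ggplot2::theme_minimal()
}
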
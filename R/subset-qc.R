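#' Map a user-defined read list onto the sequencing surface
#'
#' Reads supporting a specific biological conclusion (a list of
#' differentially expressed genes, a novel splice variant, candidate
#' structural changes...) should be scattered across the surface like any
#' random subset of the sample. This function counts the listed reads per
#' tile and returns the subset heat-map grid together with the whole-sample
#' grid, with identical layout and grid conventions, for the side-by-side
#' comparison that makes quality-driven results easy to spot.
#'
#' @param ids Normalized read identifiers (see [load_id_list()]).
#' @param reads Read tibble for the whole sample.
#' @param layout The [flowcell_layout()].
#' @return A list of class `subset_qc`: `subset` and `full` (both
#'   [sample_matrix()]-style `sample_grid` tibbles of per-tile read
#'   counts), `n_matched`, `n_unmatched`, and `test`, the
#'   [subset_uniformity_test()] of the subset against the whole sample.
#'   Errors if no id matches, naming the first five unmatched ids.
#' @export
subset_sample_matrix <- function(ids, reads, layout) {
  stopifnot(inherits(layout, "flowcell_layout"))
  norm <- normalize_read_ids(reads$read_id)
  hit <- norm %in% ids
  if (!any(hit)) {
    stopf("no id in the list matches the sample; first unmatched ids: %s",
          paste(utils::head(ids, 5L), collapse = ", "))
  }
  n_matched_ids <- sum(ids %in% norm)
  full <- tile_count_grid(reads, layout, "read_count")
  subset <- tile_count_grid(reads[hit, ], layout, "subset_read_count")
  test <- subset_uniformity_test(
    setNames(subset$value, subset$tile_id),
    setNames(full$value, full$tile_id))
  structure(list(subset = subset, full = full,
                 n_matched = sum(hit),
                 n_unmatched = length(ids) - n_matched_ids,
                 test = test),
            class = "subset_qc")
}

tile_count_grid <- function(reads, layout, metric_name) {
  tl <- layout$tiles
  counts <- table(factor(reads$tile_id, levels = tl$tile_id))
  value <- as.numeric(counts)
  missing <- tl$unused
  value[missing] <- NA_real_
  out <- tibble(tile_id = tl$tile_id, row = tl$row, col = tl$col,
                value = value, missing = missing)
  class(out) <- c("sample_grid", class(out))
  attr(out, "metric") <- metric_name
  attr(out, "scale") <- if (all(missing)) c(NA_real_, NA_real_) else
    range(value[!missing])
  attr(out, "layout") <- layout
  out
}

#' @export
print.subset_qc <- function(x, ...) {
  cat(sprintf("<subset_qc> %d reads matched (%d listed ids unmatched)\n",
              x$n_matched, x$n_unmatched))
  cat(sprintf("  uniformity: X2 = %.2f, df = %d, p = %.3g\n",
              x$test$statistic, x$test$df, x$test$p_value))
  invisible(x)
}

#' Chi-square test of a read subset against the whole-sample distribution
#'
#' Tests whether per-tile counts of a read subset are consistent with a
#' random draw from the whole sample: the expected count of tile t is
#' proportional to the full sample's count there, and the Pearson
#' chi-square statistic is compared to its asymptotic null. Tiles with
#' expected count below 5 are pooled (smallest expectations merged
#' together) to keep the asymptotics honest. The visual side-by-side
#' comparison remains the primary instrument; this test is a supplementary
#' formalization of the "deviation from random distribution" criterion.
#'
#' @param subset_counts,full_counts Numeric vectors of per-tile counts
#'   (aligned, ideally named by tile); tiles with zero/missing full count
#'   are dropped from the test.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `n_cells`
#'   (after pooling), `n_pooled` (tiles merged into pools). `df` 0 and `NA`
#'   p-value (flagged via warning) when fewer than 2 cells remain.
#' @export
subset_uniformity_test <- function(subset_counts, full_counts) {
  keep <- !is.na(full_counts) & full_counts > 0 & !is.na(subset_counts)
  o <- as.numeric(subset_counts[keep])
  f <- as.numeric(full_counts[keep])
  n <- sum(o)
  e <- f / sum(f) * n
  # pool smallest expectations until all cells reach 5
  n_pooled <- 0L
  while (length(e) > 2L && any(e < 5)) {
    ord <- order(e)
    e <- c(e[ord][1] + e[ord][2], e[ord][-(1:2)])
    o <- c(o[ord][1] + o[ord][2], o[ord][-(1:2)])
    n_pooled <- n_pooled + 1L
  }
  if (length(e) < 2L || any(e <= 0)) {
    warnf("subset uniformity test undefined: fewer than 2 usable cells")
    return(tibble(statistic = NA_real_, df = 0L, p_value = NA_real_,
                  n_cells = length(e), n_pooled = n_pooled))
  }
  stat <- sum((o - e)^2 / e)
  df <- length(e) - 1L
  tibble(statistic = stat, df = df,
         p_value = stats::pchisq(stat, df, lower.tail = FALSE),
         n_cells = length(e), n_pooled = n_pooled)
}
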
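#' Run the full QC pipeline on one sample
#'
#' Computes every QC result set for one sample in a single call: the
#' tile-metrics accumulator; sample-level heat-map grids (read count, mean
#' quality, per-symbol composition, and — when alignments are given —
#' genomic hit count); stacked x-y summaries; per-cycle composition at
#' sample and tile-column scope; the unevenness ranking of tiles; alignment
#' tallies, per-cycle mismatch rates and target-hit histograms; paired-end
#' library QC; and subset QC for each user-supplied read list.
#'
#' @param reads Read tibble ([read_fastq()], [read_csfasta()] or
#'   [simulate_flowcell()]`$reads`).
#' @param layout A [flowcell_layout()].
#' @param sam Optional path to a SAM file of alignments for these reads
#'   (or a tibble from [read_sam()]).
#' @param pair_config Optional [pair_config()]; enables pair QC on `sam`.
#' @param subsets Named list of read-id vectors (from [load_id_list()]).
#' @param grid_resolution Within-tile grid, see [tile_metrics()].
#' @param bin_size Target-histogram bin width (bp).
#' @param hist_bin Pair-distance histogram bin width (bp).
#' @param name Sample name used in the report.
#' @return A list of class `seqtileqc_run` with components `name`,
#'   `layout`, `tile_metrics`, `sample_grids` (named list of
#'   `sample_grid`s), `stacked` (named list), `cycle_composition` (sample
#'   scope), `cycle_by_column`, `unevenness`, and when inputs allow:
#'   `hit_tally`, `mismatch_rates`, `target_histogram`, `pair_summary`,
#'   `subsets` (named list of [subset_sample_matrix()] results).
#' @export
run_qc <- function(reads, layout, sam = NULL, pair_config = NULL,
                   subsets = NULL, grid_resolution = c(20L, 20L),
                   bin_size = 10000L, hist_bin = 100L, name = "sample") {
  tm <- tile_metrics(reads, layout, grid_resolution)
  first_sym <- tm$alphabet[1]
  res <- list(
    name = name, layout = layout, tile_metrics = tm,
    sample_grids = list(
      read_count = sample_matrix(tm, "read_count"),
      mean_quality = sample_matrix(tm, "mean_quality"),
      symbol_fraction = sample_matrix(tm, "symbol_fraction", symbol = first_sym)),
    stacked = list(
      read_density = stack_tiles_xy(tm, "read_density"),
      symbol_fraction = stack_tiles_xy(tm, "symbol_fraction", symbol = first_sym),
      mean_quality = stack_tiles_xy(tm, "mean_quality")),
    cycle_composition = cycle_composition(tm, "sample"),
    cycle_by_column = cycle_composition(tm, "tile_column"),
    unevenness = rank_tiles_by_unevenness(tm, "read_count")
  )
  if (!is.null(sam)) {
    hits <- if (is.character(sam)) read_sam(sam) else sam
    res$hit_tally <- tally_hits(hits, reads, layout, grid_resolution)
    res$sample_grids$hit_count <-
      sample_matrix(tm, "hit_count", tally = res$hit_tally)
    res$mismatch_rates <- mismatch_rate_per_cycle(hits)
    res$target_histogram <- target_hit_histogram(hits, bin_size)
    res$hit_unevenness <- rank_tiles_by_unevenness(tm, "hit_count",
                                                   tally = res$hit_tally)
    if (!is.null(pair_config)) {
      res$pair_summary <- summarize_pairs(hits, pair_config, hist_bin)
    }
  }
  if (length(subsets)) {
    res$subsets <- lapply(subsets, subset_sample_matrix,
                          reads = reads, layout = layout)
  }
  class(res) <- "seqtileqc_run"
  res
}

#' @export
print.seqtileqc_run <- function(x, ...) {
  cat(sprintf("<seqtileqc_run> sample '%s'\n", x$name))
  print(x$tile_metrics)
  if (!is.null(x$pair_summary)) print(x$pair_summary)
  cat(sprintf("  result sets: %s\n",
              paste(setdiff(names(x), c("name", "layout")), collapse = ", ")))
  invisible(x)
}
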
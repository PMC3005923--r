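# broom-style tidiers for the fitted/accumulated objects

#' Tidy a tile_metrics accumulator into per-tile rows
#'
#' @param x A [tile_metrics()] object.
#' @param ... Unused.
#' @return A tibble with one row per tile: position, read count, mean
#'   quality, per-symbol composition fractions, and the read-count
#'   unevenness score.
#' @method tidy tile_metrics
#' @export
tidy.tile_metrics <- function(x, ...) {
  S <- length(x$alphabet)
  called <- apply(x$cyc_counts[, , seq_len(S), drop = FALSE], 1, sum)
  qs <- rowSums(x$cyc_qual_sum); qn <- rowSums(x$cyc_qual_n)
  comp <- vapply(seq_len(S), function(s)
    ifelse(called > 0, apply(x$cyc_counts[, , s, drop = FALSE], 1, sum) / called,
           NA_real_), numeric(nrow(x$tiles)))
  colnames(comp) <- paste0("frac_", x$alphabet)
  scores <- vapply(seq_len(nrow(x$tiles)), function(t) {
    v <- x$cell_reads[t, ]
    if (sum(v) <= 0) NA_real_ else suppressWarnings(unevenness_score(v))
  }, numeric(1))
  dplyr::bind_cols(
    x$tiles[, c("tile_id", "row", "col", "unused", "read_count")],
    tibble(mean_quality = ifelse(qn > 0, qs / qn, NA_real_)),
    as_tibble(comp),
    tibble(unevenness = scores))
}

#' @rdname tidy.tile_metrics
#' @method glance tile_metrics
#' @export
glance.tile_metrics <- function(x, ...) {
  tibble(n_tiles = nrow(x$tiles),
         n_unused = sum(x$tiles$unused),
         n_reads = sum(x$tiles$read_count),
         n_cycles = x$n_cycles,
         alphabet = x$space,
         n_coordless = x$counters$n_coordless,
         n_unknown_tile = x$counters$n_unknown_tile,
         n_out_of_bounds = x$counters$n_out_of_bounds)
}

#' Tidy a sample grid into plain rows
#'
#' @param x A `sample_grid` tibble (see [sample_matrix()]).
#' @param ... Unused.
#' @return A plain tibble `tile_id`, `row`, `col`, `value`, `missing`.
#' @method tidy sample_grid
#' @export
tidy.sample_grid <- function(x, ...) {
  as_tibble(unclass(x)[c("tile_id", "row", "col", "value", "missing")])
}

#' @rdname tidy.sample_grid
#' @method glance sample_grid
#' @export
glance.sample_grid <- function(x, ...) {
  sc <- attr(x, "scale")
  tibble(metric = attr(x, "metric"), scale_min = sc[1], scale_max = sc[2],
         n_tiles = nrow(x), n_missing = sum(x$missing))
}

#' Tidy a pair summary into category counts
#'
#' @param x A [summarize_pairs()] result.
#' @param ... Unused.
#' @return The category-count tibble with a `fraction` column.
#' @method tidy pair_summary
#' @export
tidy.pair_summary <- function(x, ...) {
  dplyr::mutate(x$counts,
                fraction = if (x$n_pairs > 0) .data$n / x$n_pairs else NA_real_)
}

#' @rdname tidy.pair_summary
#' @method glance pair_summary
#' @export
glance.pair_summary <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, n_excluded = x$n_excluded,
         chimera_fraction = x$chimera_fraction,
         min_distance = x$config$min_distance,
         max_distance = x$config$max_distance)
}

#' Tidy a hit tally into per-tile bucket counts
#'
#' @param x A [tally_hits()] result.
#' @param ... Unused.
#' @return Tibble `tile_id`, `bucket`, `uniqueness`, `n`.
#' @method tidy hit_tally
#' @export
tidy.hit_tally <- function(x, ...) x$by_tile

#' @rdname tidy.hit_tally
#' @method glance hit_tally
#' @export
glance.hit_tally <- function(x, ...) {
  tibble(n_located = sum(x$by_tile$n),
         n_unmapped = sum(x$unmapped$n),
         n_unlocatable = x$n_unlocatable,
         n_unknown_nm = x$n_unknown_nm)
}

#' Tidy a composition gradient
#'
#' @param x A [composition_gradient()] result.
#' @param ... Unused.
#' @return The per-global-column profile tibble.
#' @method tidy composition_gradient
#' @export
tidy.composition_gradient <- function(x, ...) x$profile

#' @rdname tidy.composition_gradient
#' @method glance composition_gradient
#' @export
glance.composition_gradient <- function(x, ...) {
  tibble(symbol = x$symbol, slope = x$slope,
         rank_correlation = x$rank_correlation)
}
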
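#' Accumulate per-tile spatial and cycle statistics for a read table
#'
#' One pass over the reads builds, for every tile of the layout: the read
#' count, per-cycle symbol counts (bases A/C/G/T or color codes 0-3, with
#' no-calls kept separate), per-cycle quality sums, and counts binned on a
#' fixed within-tile grid — symbol counts, called-symbol totals, read counts
#' and quality sums per grid cell. Everything downstream (composition maps,
#' cycle plots, stacked x-y summaries, sample-level heat maps, unevenness
#' scores) is derived from this accumulator, so all views of a sample are
#' guaranteed to agree on the underlying counts.
#'
#' No-calls (`N` in basespace, `.` in colorspace) are excluded from
#' composition denominators — fractions are over *called* symbols — but are
#' included in read and cycle coverage counts.
#'
#' @param reads A read tibble from [read_fastq()], [read_csfasta()] or
#'   [simulate_flowcell()].
#' @param layout The [flowcell_layout()] of the run.
#' @param grid_resolution Integer vector `c(gx, gy)`: number of grid cells
#'   per tile along x and y. The default 20 x 20 makes a cell the "fixed
#'   size area" over which local composition is measured.
#' @return An object of class `tile_metrics`. Use [cycle_composition()],
#'   [spatial_composition_map()], [stack_tiles_xy()], [sample_matrix()],
#'   [rank_tiles_by_unevenness()] and [tidy()]/[glance()] to extract views.
#' @export
tile_metrics <- function(reads, layout, grid_resolution = c(20L, 20L)) {
  stopifnot(inherits(layout, "flowcell_layout"))
  grid_resolution <- as.integer(grid_resolution)
  if (length(grid_resolution) != 2L || any(grid_resolution < 1L)) {
    stopf("grid_resolution must be two integers >= 1")
  }
  space <- attr(reads, "alphabet") %||% guess_alphabet(reads$symbols)
  alphabet <- switch(space, base = c("A", "C", "G", "T"),
                     color = c("0", "1", "2", "3"),
                     stopf("unknown alphabet '%s'", space))
  no_call <- switch(space, base = "N", color = ".")
  S <- length(alphabet)
  tl <- layout$tiles
  T_ <- nrow(tl)
  gx_res <- grid_resolution[1]; gy_res <- grid_resolution[2]
  C <- gx_res * gy_res

  tile_int <- match(reads$tile_id, tl$tile_id)
  in_tile <- !is.na(tile_int)
  n <- sum(in_tile)
  L <- if (n) max(nchar(reads$symbols[in_tile])) else 0L

  cyc_counts <- array(0L, dim = c(T_, L, S + 1L),
                      dimnames = list(tl$tile_id, NULL, c(alphabet, no_call)))
  cyc_qual_sum <- matrix(0, T_, L, dimnames = list(tl$tile_id, NULL))
  cyc_qual_n <- matrix(0L, T_, L, dimnames = list(tl$tile_id, NULL))
  cell_reads <- matrix(0L, T_, C); cell_called <- matrix(0, T_, C)
  cell_sym <- array(0, dim = c(T_, C, S), dimnames = list(tl$tile_id, NULL, alphabet))
  cell_qual_sum <- matrix(0, T_, C); cell_qual_n <- matrix(0, T_, C)
  read_count <- integer(T_); no_cell <- integer(T_)

  if (n > 0L) {
    ti <- tile_int[in_tile]
    read_count <- tabulate(ti, T_)
    sym <- symbol_code_matrix(reads$symbols[in_tile], alphabet, no_call)
    qm <- qual_matrix(reads$quals[in_tile], width = L)
    for (cy in seq_len(L)) {
      v <- sym[, cy]
      keep <- !is.na(v)
      cyc_counts[, cy, ] <- cyc_counts[, cy, ] +
        matrix(tabulate((v[keep] - 1L) * T_ + ti[keep], T_ * (S + 1L)), T_, S + 1L)
    }
    qz <- qm; qz[is.na(qz)] <- 0L
    qs <- rowsum(qz, ti)
    qn <- rowsum((!is.na(qm)) * 1L, ti)
    rows_present <- as.integer(rownames(qs))
    cyc_qual_sum[rows_present, ] <- qs
    cyc_qual_n[rows_present, ] <- qn

    has_cell <- !is.na(reads$x[in_tile]) & !is.na(reads$y[in_tile])
    no_cell <- tabulate(ti[!has_cell], T_)
    if (any(has_cell)) {
      xx <- reads$x[in_tile][has_cell]; yy <- reads$y[in_tile][has_cell]
      gx <- pmin(as.integer(floor(xx / layout$tile_x * gx_res)), gx_res - 1L)
      gy <- pmin(as.integer(floor(yy / layout$tile_y * gy_res)), gy_res - 1L)
      cell0 <- gy * gx_res + gx
      grp <- (ti[has_cell] - 1L) * C + cell0 + 1L
      per_sym <- vapply(seq_len(S),
                        function(s) rowSums(sym[has_cell, , drop = FALSE] == s, na.rm = TRUE),
                        numeric(sum(has_cell)))
      per_sym <- matrix(per_sym, nrow = sum(has_cell))
      called <- rowSums(per_sym)
      qsub <- qz[has_cell, , drop = FALSE]
      qtot <- rowSums(qsub)
      qcnt <- rowSums(qn_row <- (!is.na(qm[has_cell, , drop = FALSE])) * 1L)
      agg <- rowsum(cbind(1, per_sym, called, qtot, qcnt), grp)
      g <- as.integer(rownames(agg))
      tix <- (g - 1L) %/% C + 1L
      cix <- (g - 1L) %% C + 1L
      flat <- cbind(tix, cix)
      cell_reads[flat] <- agg[, 1]
      for (s in seq_len(S)) cell_sym[cbind(tix, cix, s)] <- agg[, 1L + s]
      cell_called[flat] <- agg[, S + 2L]
      cell_qual_sum[flat] <- agg[, S + 3L]
      cell_qual_n[flat] <- agg[, S + 4L]
    }
  }

  tiles <- dplyr::mutate(tl, read_count = read_count, n_no_cell = no_cell)
  structure(list(
    layout = layout, grid_resolution = grid_resolution,
    alphabet = alphabet, no_call = no_call, space = space, n_cycles = L,
    tiles = tiles,
    cyc_counts = cyc_counts, cyc_qual_sum = cyc_qual_sum, cyc_qual_n = cyc_qual_n,
    cell_reads = cell_reads, cell_called = cell_called, cell_sym = cell_sym,
    cell_qual_sum = cell_qual_sum, cell_qual_n = cell_qual_n,
    counters = list(
      n_records = attr(reads, "n_records") %||% nrow(reads),
      n_coordless = attr(reads, "n_coordless") %||% sum(is.na(reads$tile_id)),
      n_unknown_tile = attr(reads, "n_unknown_tile") %||% 0L,
      n_out_of_bounds = attr(reads, "n_out_of_bounds") %||% 0L)
  ), class = "tile_metrics")
}

guess_alphabet <- function(symbols) {
  probe <- paste(utils::head(symbols, 100L), collapse = "")
  if (grepl("[0-3]", probe)) "color" else "base"
}

# integer symbol codes 1..S for alphabet, S+1 for no-call, NA otherwise
symbol_code_matrix <- function(symbols, alphabet, no_call) {
  lens <- nchar(symbols)
  L <- if (length(lens)) max(lens) else 0L
  lut <- rep(NA_integer_, 255L)
  lut[utf8ToInt(paste0(paste(alphabet, collapse = ""), no_call))] <-
    seq_len(length(alphabet) + 1L)
  if (all(lens == L)) {
    v <- utf8ToInt(paste(symbols, collapse = ""))
    matrix(lut[v], nrow = length(symbols), ncol = L, byrow = TRUE)
  } else {
    m <- matrix(NA_integer_, length(symbols), L)
    for (i in seq_along(symbols)) {
      if (lens[i] > 0L) m[i, seq_len(lens[i])] <- lut[utf8ToInt(symbols[i])]
    }
    m
  }
}

#' @export
print.tile_metrics <- function(x, ...) {
  cat(sprintf("<tile_metrics> %d tiles, %d cycles, %s alphabet, %d x %d grid\n",
              nrow(x$tiles), x$n_cycles, x$space,
              x$grid_resolution[1], x$grid_resolution[2]))
  cat(sprintf("  reads assigned: %d (coordinate-less: %d, unknown tile: %d, out of bounds: %d)\n",
              sum(x$tiles$read_count), x$counters$n_coordless,
              x$counters$n_unknown_tile, x$counters$n_out_of_bounds))
  invisible(x)
}

resolve_tile_groups <- function(tm, scope) {
  tl <- tm$tiles
  switch(scope,
    sample = setNames(rep("sample", nrow(tl)), tl$tile_id),
    tile_row = setNames(as.character(tl$row), tl$tile_id),
    tile_column = setNames(as.character(tl$col), tl$tile_id),
    tile = setNames(tl$tile_id, tl$tile_id),
    stopf("unknown scope '%s'", scope))
}

#' Per-cycle symbol composition
#'
#' The fraction of each base/color code among all called symbols at each
#' sequencing cycle, at sample scope or split by tile row, tile column or
#' individual tile. Splitting by tile column reproduces the view in which
#' each line traces one column of panels across the full sequencing
#' process, which exposes both cycle-specific chemistry problems (e.g.
#' periodic bias following primer-reset rounds) and spatially confined ones.
#'
#' Fractions are count-weighted pools over the scope (counts are summed
#' before dividing), so the sample-scope series equals the pooled per-tile
#' series exactly. Per cycle, fractions over the alphabet sum to 1 (within
#' floating-point) whenever any symbol was called.
#'
#' @param tm A [tile_metrics()] object.
#' @param scope `"sample"`, `"tile_row"`, `"tile_column"` or `"tile"`.
#' @return A tibble with columns `group`, `cycle` (1-based), `symbol`,
#'   `n`, `n_called`, `fraction`. Empty groups are dropped.
#' @export
cycle_composition <- function(tm, scope = c("sample", "tile_row", "tile_column", "tile")) {
  scope <- match.arg(scope)
  stopifnot(inherits(tm, "tile_metrics"))
  groups <- resolve_tile_groups(tm, scope)
  S <- length(tm$alphabet)
  L <- tm$n_cycles
  out <- vector("list", 0L)
  for (g in unique(groups)) {
    sel <- which(groups == g)
    counts <- apply(tm$cyc_counts[sel, , , drop = FALSE], c(2, 3), sum)
    if (L == 1L) counts <- matrix(counts, nrow = 1L)
    called <- rowSums(counts[, seq_len(S), drop = FALSE])
    if (sum(called) == 0) {
      inform(sprintf("cycle_composition: scope '%s' group '%s' has no called symbols", scope, g))
      next
    }
    out[[length(out) + 1L]] <- tibble(
      group = g,
      cycle = rep(seq_len(L), times = S),
      symbol = rep(tm$alphabet, each = L),
      n = as.vector(counts[, seq_len(S)]),
      n_called = rep(called, times = S),
      fraction = as.vector(counts[, seq_len(S)]) / rep(called, times = S)
    )
  }
  dplyr::bind_rows(out)
}

#' Within-tile spatial composition map
#'
#' The fraction of one symbol among all called symbols in each grid cell of
#' a tile (or pooled cell-wise over all tiles). Uneven concentration of,
#' say, A-rich reads in one region of the surface shows up as structure in
#' this map; under a well-behaved run the map is flat because fragments
#' land on the surface at random.
#'
#' @param tm A [tile_metrics()] object.
#' @param symbol A symbol of the tile's alphabet.
#' @param tile_id One tile to map, or `NULL` to pool counts cell-wise over
#'   every tile.
#' @return A tibble `gx`, `gy` (0-based cell indices), `n_called`,
#'   `fraction` (`NA` where the cell holds no called symbols).
#' @export
spatial_composition_map <- function(tm, symbol, tile_id = NULL) {
  stopifnot(inherits(tm, "tile_metrics"))
  s <- match(symbol, tm$alphabet)
  if (is.na(s)) stopf("symbol '%s' not in alphabet {%s}", symbol,
                      paste(tm$alphabet, collapse = ","))
  sel <- if (is.null(tile_id)) seq_len(nrow(tm$tiles)) else {
    i <- match(tile_id, tm$tiles$tile_id)
    if (is.na(i)) stopf("unknown tile '%s'", tile_id)
    i
  }
  sym <- colSums(tm$cell_sym[sel, , s, drop = FALSE])
  called <- colSums(tm$cell_called[sel, , drop = FALSE])
  grid_cell_tibble(tm$grid_resolution,
                   n_called = as.vector(called),
                   fraction = ifelse(called > 0, as.vector(sym) / called, NA_real_))
}

grid_cell_tibble <- function(grid_resolution, ...) {
  gx_res <- grid_resolution[1]; gy_res <- grid_resolution[2]
  tibble(gx = rep(seq_len(gx_res) - 1L, times = gy_res),
         gy = rep(seq_len(gy_res) - 1L, each = gx_res),
         ...)
}

#' Composition gradient across the chip
#'
#' Pools called-symbol counts by *global* surface column (tile column x
#' within-tile grid column) and summarizes the left-to-right trend of one
#' symbol's fraction: the weighted least-squares slope per unit chip width
#' and the rank correlation of the column fractions with column position.
#' A run with a consistent base-percentage gradient between the two ends of
#' a lane shows a nonzero slope here even when the amplitude is only 1-2%.
#'
#' @param tm A [tile_metrics()] object.
#' @param symbol Symbol whose fraction is traced.
#' @return A list of class `composition_gradient`: `profile` (tibble
#'   `global_col`, `position` in (0,1), `n_called`, `fraction`), `slope`
#'   (change of fraction across the full chip width) and
#'   `rank_correlation`.
#' @export
composition_gradient <- function(tm, symbol) {
  stopifnot(inherits(tm, "tile_metrics"))
  s <- match(symbol, tm$alphabet)
  if (is.na(s)) stopf("symbol '%s' not in alphabet", symbol)
  gx_res <- tm$grid_resolution[1]; gy_res <- tm$grid_resolution[2]
  ncol_global <- tm$layout$cols * gx_res
  gx_of_cell <- rep(seq_len(gx_res) - 1L, times = gy_res)
  tile_col <- tm$tiles$col
  sym_c <- numeric(ncol_global); called_c <- numeric(ncol_global)
  for (t in seq_len(nrow(tm$tiles))) {
    gcol <- tile_col[t] * gx_res + gx_of_cell + 1L
    sym_c <- sym_c + rowsum_vec(tm$cell_sym[t, , s], gcol, ncol_global)
    called_c <- called_c + rowsum_vec(tm$cell_called[t, ], gcol, ncol_global)
  }
  profile <- tibble(
    global_col = seq_len(ncol_global) - 1L,
    position = (seq_len(ncol_global) - 0.5) / ncol_global,
    n_called = called_c,
    fraction = ifelse(called_c > 0, sym_c / called_c, NA_real_)
  )
  keep <- !is.na(profile$fraction)
  slope <- NA_real_; rc <- NA_real_
  if (sum(keep) >= 2L) {
    fit <- stats::lm(fraction ~ position, data = profile[keep, ],
                     weights = profile$n_called[keep])
    slope <- unname(stats::coef(fit)[2])
    rc <- suppressWarnings(stats::cor(profile$fraction[keep], profile$position[keep],
                                      method = "spearman"))
  }
  structure(list(profile = profile, slope = slope, rank_correlation = rc,
                 symbol = symbol),
            class = "composition_gradient")
}

rowsum_vec <- function(v, grp, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(v, grp)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' @export
print.composition_gradient <- function(x, ...) {
  cat(sprintf("<composition_gradient> symbol %s: slope %.4f per chip width, rank correlation %.3f\n",
              x$symbol, x$slope, x$rank_correlation))
  invisible(x)
}

#' Stack all tiles at identical x-y grid positions
#'
#' Sums a per-cell quantity over every tile of the sample at the same
#' within-tile grid cell. Weak artifacts that repeat on each tile — donut
#' patterns or stripes from the image-capture optics, fluidics marks —
#' are invisible at single-tile depth but add up coherently here, while
#' tile-specific noise averages out. Pooling is count-weighted: counts are
#' summed across tiles first, then converted to a fraction or mean.
#'
#' @param tm A [tile_metrics()] object.
#' @param metric `"read_density"` (reads per cell), `"symbol_fraction"`
#'   (requires `symbol`) or `"mean_quality"`.
#' @param symbol Symbol for `metric = "symbol_fraction"`.
#' @return A tibble `gx`, `gy`, `n`, `value` (`NA` for empty cells).
#' @export
stack_tiles_xy <- function(tm, metric = c("read_density", "symbol_fraction", "mean_quality"),
                           symbol = NULL) {
  metric <- match.arg(metric)
  stopifnot(inherits(tm, "tile_metrics"))
  reads <- colSums(tm$cell_reads)
  out <- switch(metric,
    read_density = grid_cell_tibble(tm$grid_resolution, n = as.vector(reads),
                                    value = as.vector(reads)),
    symbol_fraction = {
      if (is.null(symbol)) stopf("metric 'symbol_fraction' needs a symbol")
      m <- spatial_composition_map(tm, symbol, tile_id = NULL)
      tibble(gx = m$gx, gy = m$gy, n = m$n_called, value = m$fraction)
    },
    mean_quality = {
      qs <- colSums(tm$cell_qual_sum); qn <- colSums(tm$cell_qual_n)
      grid_cell_tibble(tm$grid_resolution, n = as.vector(qn),
                       value = ifelse(qn > 0, qs / qn, NA_real_))
    })
  attr(out, "metric") <- metric
  out
}

#' Sample-level heat-map matrix of a per-tile quality measure
#'
#' One value per tile, arranged in the layout's spatial row/column grid —
#' the full-sample overview in which large-scale trends (a low-quality band
#' near the sample inlet, a gradient between the two ends of a lane) are
#' visible at a glance. Tiles unused by assay design, and tiles where the
#' measure is undefined (e.g. mean quality of an empty tile), carry `NA`
#' and are excluded from the auto-ranged scale. The heat-map scale is
#' auto-ranged: `attr(x, "scale")` is exactly the (min, max) of the
#' non-missing values.
#'
#' @param tm A [tile_metrics()] object.
#' @param metric `"read_count"`, `"mean_quality"`, `"symbol_fraction"`
#'   (requires `symbol`) or `"hit_count"` (requires `tally`).
#' @param symbol Symbol for `metric = "symbol_fraction"`.
#' @param tally A [tally_hits()] result for `metric = "hit_count"`.
#' @param unique_only For `"hit_count"`: count unique-hit reads only
#'   (default) or all mapped reads.
#' @return A tibble of class `sample_grid` with columns `tile_id`, `row`,
#'   `col`, `value`, `missing`; attributes `metric` and `scale`.
#' @export
sample_matrix <- function(tm, metric = c("read_count", "mean_quality",
                                         "symbol_fraction", "hit_count"),
                          symbol = NULL, tally = NULL, unique_only = TRUE) {
  metric <- match.arg(metric)
  stopifnot(inherits(tm, "tile_metrics"))
  tl <- tm$tiles
  value <- switch(metric,
    read_count = as.numeric(tl$read_count),
    mean_quality = {
      qs <- rowSums(tm$cyc_qual_sum); qn <- rowSums(tm$cyc_qual_n)
      ifelse(qn > 0, qs / qn, NA_real_)
    },
    symbol_fraction = {
      if (is.null(symbol)) stopf("metric 'symbol_fraction' needs a symbol")
      s <- match(symbol, tm$alphabet)
      if (is.na(s)) stopf("symbol '%s' not in alphabet", symbol)
      sym <- apply(tm$cyc_counts[, , s, drop = FALSE], 1, sum)
      called <- apply(tm$cyc_counts[, , seq_along(tm$alphabet), drop = FALSE], 1, sum)
      ifelse(called > 0, sym / called, NA_real_)
    },
    hit_count = {
      if (is.null(tally)) stopf("metric 'hit_count' needs a tally_hits() result")
      counts <- tally$by_tile
      if (unique_only) counts <- dplyr::filter(counts, .data$uniqueness == "unique")
      agg <- dplyr::summarise(dplyr::group_by(counts, .data$tile_id),
                              n = sum(.data$n), .groups = "drop")
      as.numeric(agg$n[match(tl$tile_id, agg$tile_id)] %||% NA_real_)
    })
  value <- unname(value)
  if (metric == "hit_count") value[is.na(value)] <- 0
  missing <- tl$unused | is.na(value)
  value[missing] <- NA_real_
  out <- tibble(tile_id = tl$tile_id, row = tl$row, col = tl$col,
                value = value, missing = missing)
  class(out) <- c("sample_grid", class(out))
  attr(out, "metric") <- if (metric == "symbol_fraction")
    paste0(metric, ":", symbol) else metric
  attr(out, "scale") <- if (all(missing)) c(NA_real_, NA_real_) else
    range(value[!missing])
  attr(out, "layout") <- tm$layout
  out
}

#' Fixed-grid unevenness score
#'
#' Quantifies how far a matrix of counts (reads or genomic hits per grid
#' cell) departs from spatial uniformity: the Pearson chi-square statistic
#' against the uniform expectation over non-missing cells, divided by its
#' degrees of freedom (cells - 1). The score is 0 iff every non-missing
#' cell holds the same count, and has expectation ~1 under uniform
#' scatter, so tiles with equal grids can be compared directly.
#'
#' @param cell_counts Numeric matrix or vector of per-cell counts; `NA`
#'   cells are treated as missing and excluded.
#' @return A single non-negative number, or `NA` (with a warning) when the
#'   total count is zero or fewer than two cells remain.
#' @examples
#' unevenness_score(c(25, 25, 25, 25))   # 0
#' unevenness_score(c(100, 0, 0, 0))     # 100
#' @export
unevenness_score <- function(cell_counts) {
  v <- as.numeric(cell_counts)
  v <- v[!is.na(v)]
  if (length(v) < 2L) {
    warnf("unevenness score undefined: fewer than 2 non-missing cells")
    return(NA_real_)
  }
  total <- sum(v)
  if (total <= 0) {
    warnf("unevenness score undefined: total count is zero")
    return(NA_real_)
  }
  e <- total / length(v)
  sum((v - e)^2 / e) / (length(v) - 1L)
}

#' Rank tiles by spatial unevenness
#'
#' Computes the [unevenness_score()] of every tile's within-tile grid, for
#' read counts or genomic hit counts, and orders tiles most-uneven first so
#' problematic tiles surface at the top of the report. Ties are broken by
#' tile id (lexicographic); tiles whose score is undefined (no data) are
#' listed last and flagged.
#'
#' @param tm A [tile_metrics()] object.
#' @param measure `"read_count"` or `"hit_count"`.
#' @param tally A [tally_hits()] result (required for `"hit_count"`).
#' @return A tibble `tile_id`, `score`, `total`, `flagged`, ordered by
#'   descending score.
#' @export
rank_tiles_by_unevenness <- function(tm, measure = c("read_count", "hit_count"),
                                     tally = NULL) {
  measure <- match.arg(measure)
  stopifnot(inherits(tm, "tile_metrics"))
  cells <- switch(measure,
    read_count = tm$cell_reads,
    hit_count = {
      if (is.null(tally)) stopf("measure 'hit_count' needs a tally_hits() result")
      tally$cell_hits
    })
  scores <- vapply(seq_len(nrow(tm$tiles)), function(t) {
    v <- cells[t, ]
    if (sum(v) <= 0) NA_real_ else suppressWarnings(unevenness_score(v))
  }, numeric(1))
  out <- tibble(tile_id = tm$tiles$tile_id, score = scores,
                total = rowSums(cells), flagged = is.na(scores))
  dplyr::arrange(out, .data$flagged, dplyr::desc(.data$score), .data$tile_id)
}
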
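#' Describe the tile/panel arrangement of a sequencing surface
#'
#' A flowcell layout records how the tiles (Illumina) or panels (SOLiD) of a
#' sample are arranged on the two-dimensional sequencing surface, and the x/y
#' coordinate extent within each tile. Every spatial QC computation is
#' performed against a layout: heat maps are drawn in the layout's row/column
#' arrangement, and per-read coordinates are validated against the tile
#' extents.
#'
#' Grid positions are 0-based. Tile extents are exclusive upper bounds: a
#' coordinate `x` is in bounds when `0 <= x < tile_x`. Positions listed in
#' `unused` are regions not used by the sequencing assay by design (e.g. the
#' corners of a SOLiD slide); they are carried as missing data in every
#' sample-level matrix and excluded from heat-map auto-ranging.
#'
#' @param rows,cols Number of tile rows and columns on the surface.
#' @param tile_x,tile_y Coordinate extent within each tile (exclusive upper
#'   bounds, in the platform's pixel/bead units).
#' @param platform Free-text platform label.
#' @param tile_ids Optional character vector of tile identifiers in row-major
#'   order (length `rows * cols`). Defaults to panel numbering `"1"`,
#'   `"2"`, ... Identifiers must be unique and must not contain `:`, `_` or
#'   whitespace (they are embedded in read identifiers).
#' @param unused Optional two-column matrix or data frame of 0-based
#'   `(row, col)` grid positions excluded by assay design.
#'
#' @return An object of class `flowcell_layout`: a list with elements
#'   `platform`, `rows`, `cols`, `tile_x`, `tile_y` and `tiles`, a tibble
#'   with columns `tile_id`, `row`, `col`, `unused`.
#' @examples
#' layout <- flowcell_layout(3, 2, tile_x = 1000, tile_y = 2000)
#' layout$tiles
#' @export
flowcell_layout <- function(rows, cols, tile_x = 1000L, tile_y = 1000L,
                            platform = "generic", tile_ids = NULL,
                            unused = NULL) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  tile_x <- as.integer(tile_x); tile_y <- as.integer(tile_y)
  if (rows < 1L || cols < 1L) stopf("layout must have at least one row and column")
  if (tile_x < 1L || tile_y < 1L) stopf("tile extents must be strictly positive")
  n <- rows * cols
  tile_ids <- tile_ids %||% as.character(seq_len(n))
  if (length(tile_ids) != n) stopf("need %d tile ids, got %d", n, length(tile_ids))
  if (anyDuplicated(tile_ids)) {
    stopf("duplicate tile_id: %s", tile_ids[duplicated(tile_ids)][1])
  }
  if (any(grepl("[:_[:space:]]", tile_ids))) {
    stopf("tile ids must not contain ':', '_' or whitespace")
  }
  tiles <- tibble(
    tile_id = tile_ids,
    row = rep(seq_len(rows) - 1L, each = cols),
    col = rep(seq_len(cols) - 1L, times = rows),
    unused = FALSE
  )
  if (!is.null(unused)) {
    unused <- as.matrix(unused)
    if (ncol(unused) != 2L) stopf("'unused' needs (row, col) pairs")
    idx <- unused[, 1] * cols + unused[, 2] + 1L
    if (any(idx < 1L | idx > n)) stopf("'unused' position outside the grid")
    tiles$unused[idx] <- TRUE
  }
  structure(
    list(platform = platform, rows = rows, cols = cols,
         tile_x = tile_x, tile_y = tile_y, tiles = tiles),
    class = "flowcell_layout"
  )
}

#' @export
print.flowcell_layout <- function(x, ...) {
  cat(sprintf(
    "<flowcell_layout> %s: %d x %d tiles (%d unused), tile extent %d x %d\n",
    x$platform, x$rows, x$cols, sum(x$tiles$unused), x$tile_x, x$tile_y))
  invisible(x)
}

#' Read or write a layout-definition file
#'
#' Layout files are plain ASCII, one per supported platform/assay format.
#' The schema (version 1) is a `key: value` header followed by one line per
#' tile:
#'
#' ```
#' platform: Illumina-mini
#' rows: 3
#' cols: 2
#' tile_x: 1000
#' tile_y: 2000
#' 0 0 1
#' 0 1 2
#' ...
#' 2 1 6 unused
#' ```
#'
#' Tile lines are `row col tile_id [unused]` with 0-based grid positions.
#' Lines starting with `#` and blank lines are ignored. Grid positions not
#' listed are treated as unused by design.
#'
#' @param path File to read or write.
#' @param layout A `flowcell_layout` (for writing).
#' @return `parse_layout_file()` returns a [flowcell_layout()];
#'   `write_layout_file()` returns `path` invisibly.
#' @export
parse_layout_file <- function(path) {
  lines <- readr::read_lines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  header <- list()
  tile_rows <- list()
  for (i in keep) {
    ln <- trimws(lines[i])
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*:\\s*(.+)$", ln))[[1]]
    if (length(m) == 3L) {
      header[[m[2]]] <- m[3]
      next
    }
    f <- strsplit(ln, "\\s+")[[1]]
    if (!(length(f) %in% c(3L, 4L)) || anyNA(suppressWarnings(as.integer(f[1:2])))) {
      stopf("layout file %s, line %d: malformed line '%s'", path, i, ln)
    }
    if (length(f) == 4L && f[4] != "unused") {
      stopf("layout file %s, line %d: unexpected token '%s'", path, i, f[4])
    }
    tile_rows[[length(tile_rows) + 1L]] <- list(
      row = as.integer(f[1]), col = as.integer(f[2]), tile_id = f[3],
      unused = length(f) == 4L, line = i)
  }
  need <- c("rows", "cols", "tile_x", "tile_y")
  miss <- setdiff(need, names(header))
  if (length(miss)) stopf("layout file %s: missing header key(s): %s",
                          path, paste(miss, collapse = ", "))
  rows <- as.integer(header$rows); cols <- as.integer(header$cols)
  tile_x <- as.integer(header$tile_x); tile_y <- as.integer(header$tile_y)
  if (anyNA(c(rows, cols, tile_x, tile_y)) || tile_x <= 0L || tile_y <= 0L) {
    stopf("layout file %s: header extents must be positive integers", path)
  }
  if (!length(tile_rows)) stopf("layout file %s: no tile lines", path)
  tl <- dplyr::bind_rows(lapply(tile_rows, as_tibble))
  dup <- which(duplicated(tl$tile_id))
  if (length(dup)) {
    stopf("layout file %s, line %d: duplicate tile_id '%s'",
          path, tl$line[dup[1]], tl$tile_id[dup[1]])
  }
  bad <- tl$row < 0L | tl$row >= rows | tl$col < 0L | tl$col >= cols
  if (any(bad)) stopf("layout file %s, line %d: grid position (%d, %d) outside %d x %d",
                      path, tl$line[bad][1], tl$row[bad][1], tl$col[bad][1], rows, cols)
  pos <- tl$row * cols + tl$col
  if (anyDuplicated(pos)) stopf("layout file %s: duplicate grid position", path)
  ids <- rep(NA_character_, rows * cols)
  unused_flag <- rep(TRUE, rows * cols)
  ids[pos + 1L] <- tl$tile_id
  unused_flag[pos + 1L] <- tl$unused
  # grid cells never listed still need placeholder ids
  missing_cells <- which(is.na(ids))
  if (length(missing_cells)) ids[missing_cells] <- paste0("na", missing_cells)
  un <- which(unused_flag) - 1L
  flowcell_layout(rows, cols, tile_x, tile_y,
                  platform = header$platform %||% "unknown",
                  tile_ids = ids,
                  unused = if (length(un)) cbind(un %/% cols, un %% cols))
}

#' @rdname parse_layout_file
#' @export
write_layout_file <- function(layout, path) {
  stopifnot(inherits(layout, "flowcell_layout"))
  t <- layout$tiles
  lines <- c(
    sprintf("platform: %s", layout$platform),
    sprintf("rows: %d", layout$rows),
    sprintf("cols: %d", layout$cols),
    sprintf("tile_x: %d", layout$tile_x),
    sprintf("tile_y: %d", layout$tile_y),
    sprintf("%d %d %s%s", t$row, t$col, t$tile_id, ifelse(t$unused, " unused", ""))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Built-in miniature layouts
#'
#' `layout_mini()` is a 5 x 4 tile chip with 1000 x 1000 tile extents,
#' emulating one Illumina-style lane at reduced scale. `layout_slide_mini()`
#' is a 6 x 10 panel slide whose four corner panels are unused by design,
#' emulating a SOLiD slide at reduced scale.
#'
#' @return A [flowcell_layout()].
#' @export
layout_mini <- function() {
  flowcell_layout(5, 4, 1000, 1000, platform = "mini-chip")
}

#' @rdname layout_mini
#' @export
layout_slide_mini <- function() {
  corners <- rbind(c(0, 0), c(0, 9), c(5, 0), c(5, 9))
  flowcell_layout(6, 10, 500, 500, platform = "mini-slide", unused = corners)
}
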
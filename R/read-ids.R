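#' Extract surface coordinates from read identifiers
#'
#' Sequencing platforms encode the capture tile/panel and the within-tile
#' x/y position of every read in its identifier, which is what links a read
#' back to a physical location on the sequencing surface. Three dialects are
#' supported:
#'
#' * `"legacy"` — colon-delimited Illumina names of the form
#'   `machine:lane:tile:x:y#index/mate`, e.g.
#'   `HWUSI-EAS100R:6:73:941:1973#0/1`.
#' * `"casava18"` — 7-field CASAVA 1.8+ names,
#'   `instrument:run:flowcell:lane:tile:x:y mate:filter:0:index`, e.g.
#'   `M1:RUN:FC:1:1101:5:7 1:N:0:ACGT`.
#' * `"solid"` — underscore-delimited SOLiD bead names `panel_x_y_tag`,
#'   e.g. `1_52_85_F3` (a leading `>` is tolerated).
#'
#' With `dialect = "auto"` the dialect is detected from the first
#' parseable identifier and then fixed for the whole vector, mirroring the
#' per-file convention of real runs. Identifiers that do not parse are
#' returned with `ok = FALSE` ("coordinate-less" reads); they are counted,
#' never dropped silently, by the file readers.
#'
#' @param ids Character vector of read identifiers.
#' @param dialect One of `"auto"`, `"legacy"`, `"casava18"`, `"solid"`.
#' @return A tibble with columns `read_id`, `tile_id`, `x`, `y`, `mate`
#'   (character: `"1"`/`"2"` or a SOLiD tag such as `"F3"`) and `ok`.
#'   Coordinate fields are `NA` where `ok` is `FALSE`.
#' @examples
#' parse_read_ids("HWUSI-EAS100R:6:73:941:1973#0/1")
#' parse_read_ids(">429_1003_22_R3")
#' @export
parse_read_ids <- function(ids, dialect = c("auto", "legacy", "casava18", "solid")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- detect_id_dialect(ids)
  }
  re <- switch(dialect,
    legacy   = "^[^:[:space:]]+:[0-9]+:([0-9]+):([0-9]+):([0-9]+)(?:#[^/[:space:]]*)?(?:/([12]))?$",
    casava18 = "^[^:[:space:]]+:[^:[:space:]]+:[^:[:space:]]+:[0-9]+:([0-9]+):([0-9]+):([0-9]+)[[:space:]]+([12]):.*$",
    solid    = "^>?([^_[:space:]]+)_([0-9]+)_([0-9]+)(?:_([^_[:space:]]+))?$"
  )
  m <- regmatches(ids, regexec(re, ids))
  ok <- lengths(m) == 5L
  g <- function(k) vapply(m[ok], `[[`, character(1), k + 1L)
  out <- tibble(
    read_id = ids,
    tile_id = NA_character_, x = NA_integer_, y = NA_integer_,
    mate = NA_character_, ok = ok
  )
  if (any(ok)) {
    if (dialect == "casava18") {
      out$tile_id[ok] <- g(1); out$x[ok] <- as.integer(g(2))
      out$y[ok] <- as.integer(g(3)); out$mate[ok] <- g(4)
    } else {
      out$tile_id[ok] <- g(1); out$x[ok] <- as.integer(g(2))
      out$y[ok] <- as.integer(g(3))
      mt <- g(4)
      out$mate[ok] <- ifelse(mt == "", if (dialect == "solid") NA_character_ else "1", mt)
    }
  }
  attr(out, "dialect") <- dialect
  out
}

detect_id_dialect <- function(ids) {
  probe <- utils::head(ids[!is.na(ids)], 50L)
  for (d in c("casava18", "legacy", "solid")) {
    r <- parse_read_ids(probe, dialect = d)
    if (any(r$ok)) return(d)
  }
  "casava18"
}

#' Normalize read identifiers for matching across files
#'
#' Strips everything that differs between representations of the same
#' physical read: the CASAVA description after the first whitespace, `#index`
#' suffixes, `/1`-`/2` mate suffixes, and SOLiD tag suffixes (`_F3`, `_R3`,
#' `_F5*`, `_BC`), plus a leading `>` or `@`. Used when matching alignment
#' records and user-supplied read lists against read files.
#'
#' @param ids Character vector of read identifiers.
#' @return Character vector of normalized identifiers.
#' @examples
#' normalize_read_ids(c("r7/1", "r7/2", "@r7#0/1", ">12_4_8_F3"))
#' @export
normalize_read_ids <- function(ids) {
  x <- sub("^[>@]", "", ids)
  x <- sub("[[:space:]].*$", "", x)
  x <- sub("#[^/]*", "", x)
  x <- sub("/[12]$", "", x)
  sub("_(F3|R3|F5[-A-Za-z0-9]*|BC)$", "", x)
}

# format a read id in a given dialect (used by the simulator)
format_read_id <- function(dialect, tile_id, x, y, mate, prefix = "SIM") {
  switch(dialect,
    legacy = sprintf("%s:1:%s:%d:%d#0/%s", prefix, tile_id, x, y, mate),
    casava18 = sprintf("%s:1:FC1:1:%s:%d:%d %s:N:0:ACGT", prefix, tile_id, x, y, mate),
    solid = sprintf("%d_%d_%d_%s", as.integer(tile_id), x, y, mate)
  )
}
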
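#' Read a FASTQ file into a read table
#'
#' Reads 4-line FASTQ records and extracts the surface coordinate of every
#' read from its identifier. The quality encoding (Phred+33 vs Phred+64) is
#' autodetected by a value-range scan of up to the first 10,000 records:
#' any character below `;` forces +33, any character above `J` forces +64,
#' and an ambiguous range defaults to +33 with a warning. Qualities are
#' re-encoded to Phred+33 in the returned table regardless of the input
#' encoding.
#'
#' Reads whose identifiers cannot be parsed into a coordinate, whose tile is
#' absent from the layout, or whose x/y fall outside the tile extents are
#' kept in the table with `NA` coordinates and counted (see the attributes
#' below); the file is rejected outright only when more than half of the
#' first 1000 identifiers fail to parse. Platform x/y values are shifted to
#' 0-based by subtracting the per-file minimum before bounds checking.
#'
#' @param path FASTQ file (4-line records, uncompressed or gzipped).
#' @param layout Optional [flowcell_layout()] used to validate tiles and
#'   coordinates.
#' @param dialect Read-identifier dialect, see [parse_read_ids()].
#' @return A tibble with columns `read_id`, `tile_id`, `x`, `y`, `mate`,
#'   `symbols`, `quals` (Phred+33 string), carrying attributes `alphabet`
#'   (`"base"`), `qual_offset` (detected input offset), `n_records`,
#'   `n_coordless`, `n_unknown_tile`, `n_out_of_bounds`.
#' @seealso [read_csfasta()] for SOLiD colorspace input.
#' @export
read_fastq <- function(path, layout = NULL, dialect = "auto") {
  n_lines <- length(readr::read_lines(path, progress = FALSE))
  if (n_lines == 0L) {
    warnf("empty FASTQ file: %s", path)
    return(empty_reads("base"))
  }
  if (n_lines %% 4L != 0L) {
    stopf("truncated FASTQ record in %s: %d lines is not a multiple of 4 (near line %d)",
          path, n_lines, (n_lines %/% 4L) * 4L + 1L)
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  quals <- as.character(S4Vectors::mcols(x)$qualities)
  offset <- detect_phred_offset(quals)
  if (offset == 64L) {
    quals <- vapply(quals, function(s) intToUtf8(utf8ToInt(s) - 31L), character(1),
                    USE.NAMES = FALSE)
  }
  build_reads(names(x), unname(as.character(x)), unname(quals), alphabet = "base",
              layout = layout, dialect = dialect, qual_offset = offset,
              source = path)
}

#' Read a SOLiD csfasta + qual file pair
#'
#' SOLiD colorspace reads come as two parallel files: a `.csfasta` file with
#' a leading primer base followed by color codes 0-3 (`.` for a missed
#' call), and a `.qual` file with one Phred score per color call. Headers of
#' the two files must pair up 1:1 in order; `#`-prefixed comment lines are
#' skipped. The primer base is kept as metadata (attribute `primers`), so
#' `symbols` holds exactly the color calls that the quality scores align to.
#' `.` color calls are no-calls: they are kept in the symbol string, counted
#' in read counts, and excluded from composition denominators downstream.
#'
#' @param csfasta_path,qual_path The paired SOLiD files.
#' @param layout Optional [flowcell_layout()].
#' @return A tibble shaped like [read_fastq()]'s, with attribute `alphabet`
#'   set to `"color"` and attribute `primers` holding the per-read primer
#'   base.
#' @export
read_csfasta <- function(csfasta_path, qual_path, layout = NULL) {
  cs <- read_solid_records(csfasta_path)
  qv <- read_solid_records(qual_path)
  if (length(cs$header) != length(qv$header)) {
    k <- min(length(cs$header), length(qv$header))
    first_diff <- if (k == 0L) 1L else k + 1L
    stopf("csfasta/qual record count mismatch (%d vs %d); first unmatched header: '%s'",
          length(cs$header), length(qv$header),
          c(cs$header, qv$header)[first_diff])
  }
  if (length(cs$header) == 0L) {
    warnf("empty csfasta file: %s", csfasta_path)
    return(empty_reads("color"))
  }
  div <- which(cs$header != qv$header)
  if (length(div)) {
    stopf("csfasta/qual headers diverge at record %d: '%s' vs '%s'",
          div[1], cs$header[div[1]], qv$header[div[1]])
  }
  primer <- substr(cs$body, 1L, 1L)
  colors <- substr(cs$body, 2L, nchar(cs$body))
  qints <- lapply(strsplit(trimws(qv$body), "\\s+"), as.integer)
  nsym <- nchar(colors)
  bad <- which(lengths(qints) != nsym)
  if (length(bad)) {
    stopf("record '%s': %d color calls but %d quality values",
          cs$header[bad[1]], nsym[bad[1]], lengths(qints)[bad[1]])
  }
  quals <- vapply(qints, function(v) phred_encode(pmax(v, 0L)), character(1))
  out <- build_reads(cs$header, colors, quals, alphabet = "color",
                     layout = layout, dialect = "solid", qual_offset = 33L,
                     source = csfasta_path)
  attr(out, "primers") <- primer
  out
}

# parse a csfasta-style file into (header, body) pairs; bodies may not wrap
read_solid_records <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  h <- which(hdr)
  if (length(lines) && (length(h) * 2L != length(lines) || any(h != seq(1L, length(lines), by = 2L)))) {
    stopf("%s: malformed record structure (expected alternating '>' header and record lines)", path)
  }
  list(header = sub("^>", "", lines[hdr]), body = lines[!hdr])
}

detect_phred_offset <- function(quals, n_probe = 10000L) {
  probe <- utils::head(quals, n_probe)
  if (!length(probe)) return(33L)
  codes <- utf8ToInt(paste(probe, collapse = ""))
  if (!length(codes)) return(33L)
  if (min(codes) < 59L) return(33L)   # below ';' impossible under +64
  if (max(codes) > 74L) return(64L)   # above 'J' impossible under +33
  warnf("ambiguous quality encoding (range %s-%s); assuming Phred+33",
        intToUtf8(min(codes)), intToUtf8(max(codes)))
  33L
}

empty_reads <- function(alphabet) {
  out <- tibble(read_id = character(), tile_id = character(), x = integer(),
                y = integer(), mate = character(), symbols = character(),
                quals = character())
  attr(out, "alphabet") <- alphabet
  attr(out, "qual_offset") <- 33L
  attr(out, "n_records") <- 0L
  attr(out, "n_coordless") <- 0L
  attr(out, "n_unknown_tile") <- 0L
  attr(out, "n_out_of_bounds") <- 0L
  out
}

build_reads <- function(ids, symbols, quals, alphabet, layout, dialect,
                        qual_offset, source = "<reads>") {
  coords <- parse_read_ids(ids, dialect = dialect)
  probe_n <- min(length(ids), 1000L)
  if (probe_n > 0L && sum(!coords$ok[seq_len(probe_n)]) > probe_n / 2) {
    stopf("%s: >50%% of the first %d read ids have no parseable surface coordinate",
          source, probe_n)
  }
  n_coordless <- sum(!coords$ok)
  n_unknown <- 0L; n_oob <- 0L
  if (!is.null(layout)) {
    known <- coords$ok & coords$tile_id %in% layout$tiles$tile_id
    n_unknown <- sum(coords$ok & !known)
    coords$tile_id[!known] <- NA_character_
    # platform coordinates are made 0-based against the per-file minimum
    if (any(known)) {
      coords$x[known] <- coords$x[known] - min(coords$x[known])
      coords$y[known] <- coords$y[known] - min(coords$y[known])
      oob <- known & (coords$x >= layout$tile_x | coords$y >= layout$tile_y)
      n_oob <- sum(oob)
      coords$x[oob] <- NA_integer_
      coords$y[oob] <- NA_integer_
    }
  }
  out <- tibble(
    read_id = ids, tile_id = coords$tile_id, x = coords$x, y = coords$y,
    mate = coords$mate, symbols = symbols, quals = quals
  )
  attr(out, "alphabet") <- alphabet
  attr(out, "qual_offset") <- qual_offset
  attr(out, "n_records") <- length(ids)
  attr(out, "n_coordless") <- n_coordless
  attr(out, "n_unknown_tile") <- n_unknown
  attr(out, "n_out_of_bounds") <- n_oob
  attr(out, "dialect") <- attr(coords, "dialect")
  out
}

#' Parse a paired-end configuration file
#'
#' The pair configuration is a two-line plain-text file. The first line
#' `pair: <END1> <END2>` names the two read files holding the two ends of
#' the library; the second line `range: <min> <max>` gives the expected
#' minimum and maximum distance in bp between the two ends. Pairs whose ends
#' map closer than `min` or farther than `max` apart are classified as
#' abnormal.
#'
#' @param path Pair-configuration file.
#' @return A list of class `pair_config` with elements `end1_file`,
#'   `end2_file`, `min_distance`, `max_distance`.
#' @examples
#' p <- tempfile()
#' writeLines(c("pair: end1.fq end2.fq", "range: 500 5000"), p)
#' parse_pair_config(p)
#' @export
parse_pair_config <- function(path) {
  lines <- trimws(readr::read_lines(path, progress = FALSE))
  lines <- lines[nzchar(lines)]
  pair_ln <- grep("^pair:", lines, value = TRUE)
  range_ln <- grep("^range:", lines, value = TRUE)
  if (length(pair_ln) != 1L) stopf("pair config %s: need exactly one 'pair:' line", path)
  if (length(range_ln) != 1L) stopf("pair config %s: need exactly one 'range:' line", path)
  ends <- strsplit(trimws(sub("^pair:", "", pair_ln)), "\\s+")[[1]]
  if (length(ends) != 2L) stopf("pair config %s: 'pair:' line must name two files", path)
  rng <- suppressWarnings(as.integer(strsplit(trimws(sub("^range:", "", range_ln)), "\\s+")[[1]]))
  if (length(rng) != 2L || anyNA(rng)) {
    stopf("pair config %s: 'range:' line must give two integers", path)
  }
  pair_config(ends[1], ends[2], rng[1], rng[2])
}

#' @rdname parse_pair_config
#' @param end1_file,end2_file Read files for the two ends.
#' @param min_distance,max_distance Expected library separation range in bp,
#'   `0 < min < max`.
#' @export
pair_config <- function(end1_file = "end1", end2_file = "end2",
                        min_distance = 500L, max_distance = 5000L) {
  min_distance <- as.integer(min_distance)
  max_distance <- as.integer(max_distance)
  if (!(min_distance > 0L && min_distance < max_distance)) {
    stopf("pair range must satisfy 0 < min < max (got %d, %d)",
          min_distance, max_distance)
  }
  structure(list(end1_file = end1_file, end2_file = end2_file,
                 min_distance = min_distance, max_distance = max_distance),
            class = "pair_config")
}

#' Load a user-supplied read-identifier list
#'
#' One identifier per line; blank lines are ignored. Identifiers are
#' normalized with [normalize_read_ids()] (mate and index suffixes stripped)
#' and duplicates are collapsed with a message. These lists name the reads
#' behind a specific biological conclusion so their spatial distribution can
#' be compared against the whole sample (see [subset_sample_matrix()]).
#'
#' @param path Text file of read identifiers.
#' @return Character vector of unique normalized identifiers, with
#'   attribute `n_duplicates`.
#' @export
load_id_list <- function(path) {
  ids <- trimws(readr::read_lines(path, progress = FALSE))
  ids <- ids[nzchar(ids)]
  if (!length(ids)) stopf("read-id list %s is empty", path)
  norm <- normalize_read_ids(ids)
  n_dup <- sum(duplicated(norm))
  if (n_dup > 0L) inform(sprintf("%s: collapsed %d duplicate id(s)", path, n_dup))
  out <- unique(norm)
  attr(out, "n_duplicates") <- n_dup
  out
}
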
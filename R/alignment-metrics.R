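#' Tally genomic hits per tile by mismatch count and uniqueness
#'
#' Collapses alignment records to one outcome per read end and assigns it
#' to the read's tile: hits are bucketed by best-hit mismatch count
#' (`0`, `1`, `2`, `>=3`) and by hit level (`unique` — exactly one mapped
#' location — vs `multiple`), with unmapped reads tallied separately. The
#' per-tile genomic hit count is typically the most sensitive spatial
#' quality measure: regional quality defects that barely move base
#' composition or vendor quality scores show up amplified in the hit map.
#'
#' Mapped reads whose mismatch count is unknown (no NM tag) are counted in
#' an `"unknown"` bucket and excluded from the mismatch-criterion buckets.
#' Hits whose read id cannot be located on the surface are counted as
#' unlocatable.
#'
#' @param hits Alignment tibble from [read_sam()].
#' @param reads Read tibble providing surface coordinates (matched on
#'   normalized read id + mate).
#' @param layout,grid_resolution Layout and within-tile grid used for the
#'   per-cell hit counts that feed [rank_tiles_by_unevenness()].
#' @return An object of class `hit_tally`: list with `by_tile` (tibble
#'   `tile_id`, `bucket`, `uniqueness`, `n`), `unmapped` (tibble `tile_id`,
#'   `n`), `cell_hits` (tile x grid-cell matrix of located mapped reads),
#'   `n_unlocatable`, `n_unknown_nm`.
#' @export
tally_hits <- function(hits, reads, layout, grid_resolution = c(20L, 20L)) {
  stopifnot(inherits(layout, "flowcell_layout"))
  grid_resolution <- as.integer(grid_resolution)
  # collapse to one outcome per read end
  key <- paste(hits$read_id, hits$mate)
  mapped <- hits$mapped
  ord <- order(key, !mapped, hits$mismatches, na.last = TRUE)
  h <- hits[ord, ]
  first <- h[!duplicated(paste(h$read_id, h$mate)), ]
  n_hits <- as.vector(table(key[mapped])[paste(first$read_id, first$mate)])
  n_hits[is.na(n_hits)] <- 0L
  outcome <- tibble(
    read_id = first$read_id, mate = first$mate,
    mapped = first$mapped,
    best_nm = first$mismatches,
    uniqueness = dplyr::case_when(!first$mapped ~ NA_character_,
                                  n_hits == 1L ~ "unique",
                                  TRUE ~ "multiple")
  )
  # locate each read end on the surface
  rkey <- paste(normalize_read_ids(reads$read_id), reads$mate %||% "1")
  okey <- paste(outcome$read_id, outcome$mate)
  ridx <- match(okey, rkey)
  # single-end alignments of single-end reads may disagree on the mate label
  miss <- is.na(ridx)
  if (any(miss)) ridx[miss] <- match(outcome$read_id[miss], normalize_read_ids(reads$read_id))
  located <- !is.na(ridx) & !is.na(reads$tile_id[ridx])
  n_unlocatable <- sum(!located)
  tile_id <- reads$tile_id[ridx]
  xx <- reads$x[ridx]; yy <- reads$y[ridx]

  buckets <- c("0", "1", "2", ">=3", "unknown")
  bucket <- dplyr::case_when(
    !outcome$mapped ~ NA_character_,
    is.na(outcome$best_nm) ~ "unknown",
    outcome$best_nm >= 3L ~ ">=3",
    TRUE ~ as.character(outcome$best_nm))
  keep <- located & outcome$mapped
  by_tile <- dplyr::count(
    tibble(tile_id = tile_id[keep],
           bucket = factor(bucket[keep], levels = buckets),
           uniqueness = outcome$uniqueness[keep]),
    .data$tile_id, .data$bucket, .data$uniqueness, name = "n", .drop = FALSE)
  by_tile <- dplyr::mutate(by_tile, bucket = as.character(.data$bucket))
  unmapped <- dplyr::count(tibble(tile_id = tile_id[located & !outcome$mapped]),
                           .data$tile_id, name = "n")

  gx_res <- grid_resolution[1]; gy_res <- grid_resolution[2]
  C <- gx_res * gy_res
  T_ <- nrow(layout$tiles)
  cell_hits <- matrix(0L, T_, C, dimnames = list(layout$tiles$tile_id, NULL))
  cl <- keep & !is.na(xx) & !is.na(yy)
  if (any(cl)) {
    ti <- match(tile_id[cl], layout$tiles$tile_id)
    gx <- pmin(as.integer(floor(xx[cl] / layout$tile_x * gx_res)), gx_res - 1L)
    gy <- pmin(as.integer(floor(yy[cl] / layout$tile_y * gy_res)), gy_res - 1L)
    grp <- (gy * gx_res + gx) * T_ + ti
    tab <- tabulate(grp, T_ * C)
    cell_hits <- matrix(tab, T_, C, byrow = FALSE,
                        dimnames = list(layout$tiles$tile_id, NULL))
  }
  structure(list(by_tile = by_tile, unmapped = unmapped, cell_hits = cell_hits,
                 n_unlocatable = n_unlocatable,
                 n_unknown_nm = sum(bucket == "unknown", na.rm = TRUE),
                 layout = layout, grid_resolution = grid_resolution),
            class = "hit_tally")
}

#' @export
print.hit_tally <- function(x, ...) {
  cat(sprintf("<hit_tally> %d located outcomes over %d tiles (unlocatable: %d, unknown NM: %d)\n",
              sum(x$by_tile$n) + sum(x$unmapped$n), nrow(x$layout$tiles),
              x$n_unlocatable, x$n_unknown_nm))
  invisible(x)
}

#' Mismatch rate per sequencing cycle
#'
#' The fraction of reads mismatching the reference at each base position
#' along the read, derived from unique genome hits only (multiple hits are
#' ambiguous about which mismatches are real). Rising rates toward late
#' cycles indicate chemistry decay; isolated spikes indicate cycle-specific
#' problems. The mismatch mask is reconstructed from the MD tag of
#' indel-free alignments, flipped into read-cycle order for minus-strand
#' hits; with ragged read lengths the denominator at cycle c is the number
#' of reads covering c.
#'
#' @param hits Alignment tibble from [read_sam()].
#' @return A tibble `cycle` (1-based), `n_reads`, `n_mismatch`, `rate`;
#'   attribute `n_reads_used` gives the number of unique indel-free hits
#'   entering the rates. Zero rows (with a message) when no usable hits
#'   exist.
#' @export
mismatch_rate_per_cycle <- function(hits) {
  use <- hits$mapped & hits$unique & !is.na(hits$mismatches) &
    !is.na(hits$md) & is_simple_cigar(hits$cigar)
  h <- hits[use, ]
  if (!nrow(h)) {
    inform("mismatch_rate_per_cycle: no unique indel-free hits with MD tags")
    out <- tibble(cycle = integer(), n_reads = integer(),
                  n_mismatch = integer(), rate = numeric())
    attr(out, "n_reads_used") <- 0L
    return(out)
  }
  L <- max(h$read_length)
  n_reads <- vapply(seq_len(L), function(cy) sum(h$read_length >= cy), integer(1))
  n_mm <- integer(L)
  with_mm <- which(h$mismatches > 0L)
  for (i in with_mm) {
    cyc <- md_mismatch_cycles(h$md[i], h$strand[i], h$read_length[i])
    if (is.null(cyc)) next
    n_mm[cyc + 1L] <- n_mm[cyc + 1L] + 1L
  }
  out <- tibble(cycle = seq_len(L), n_reads = n_reads, n_mismatch = n_mm,
                rate = n_mm / n_reads)
  attr(out, "n_reads_used") <- nrow(h)
  out
}

#' Histogram of alignment starts along the reference
#'
#' Bins mapped reads by alignment start position for every reference
#' sequence, exposing uneven coverage of the target genome/transcriptome
#' and large-scale sample-vs-reference structural differences. Each read is
#' counted once, at its (best-hit) start position's bin; by default only
#' unique hits are counted.
#'
#' @param hits Alignment tibble from [read_sam()].
#' @param bin_size Bin width in bp (>= 1).
#' @param unique_only Count unique hits only (default) or the best hit of
#'   every mapped read.
#' @param reference_lengths Named vector of reference lengths; defaults to
#'   the `targets` attribute captured from the SAM header.
#' @return A tibble `reference`, `bin_start`, `bin_end`, `count`, covering
#'   every bin of every reference (zeros included).
#' @export
target_hit_histogram <- function(hits, bin_size, unique_only = TRUE,
                                 reference_lengths = NULL) {
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size < 1L) stopf("bin_size must be >= 1")
  targets <- reference_lengths %||% attr(hits, "targets")
  if (is.null(targets)) stopf("no reference lengths: pass reference_lengths or use read_sam() output")
  h <- hits[hits$mapped & (!unique_only | hits$unique), ]
  # one count per read end: keep the best (fewest-mismatch) hit
  ord <- order(paste(h$read_id, h$mate), h$mismatches, na.last = TRUE)
  h <- h[ord, ][!duplicated(paste(h$read_id, h$mate)[ord]), ]
  bad <- setdiff(unique(h$reference), names(targets))
  if (length(bad)) stopf("reference '%s' absent from the SAM header", bad[1])
  out <- lapply(names(targets), function(ref) {
    len <- targets[[ref]]
    nb <- max(1L, as.integer(ceiling(len / bin_size)))
    starts <- h$start[h$reference == ref]
    counts <- tabulate(pmin(starts %/% bin_size, nb - 1L) + 1L, nb)
    tibble(reference = ref,
           bin_start = (seq_len(nb) - 1L) * bin_size,
           bin_end = pmin(seq_len(nb) * bin_size, len),
           count = counts)
  })
  dplyr::bind_rows(out)
}
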
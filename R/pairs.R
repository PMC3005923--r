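pair_category_levels <- c("good_pair", "unpaired_forward", "unpaired_reverse",
                          "different_chromosome", "wrong_orientation",
                          "below_range", "above_range")

#' Signed distance between the two ends of a pair
#'
#' The distance between a pair is the starting position of the first end
#' minus the starting position of the second end, so distance values can be
#' negative; the sign carries the relative order of the two ends on the
#' reference. Both ends must be mapped to the same reference for the
#' distance to be meaningful.
#'
#' @param start1,start2 0-based alignment start positions of the two ends.
#' @return `start1 - start2` (vectorized).
#' @examples
#' pair_distance(100, 600)   # -500
#' pair_distance(5000, 100)  # 4900
#' @export
pair_distance <- function(start1, start2) start1 - start2

#' Classify read pairs into library-QC categories
#'
#' Each pair with at least one usable end falls into exactly one of six
#' categories: `good_pair` (both ends on the same chromosome, convergent
#' orientation, separation within the expected library range),
#' `unpaired_forward` / `unpaired_reverse` (only end 1 / only end 2
#' usable — the two ends are kept separate because reading efficiency can
#' differ between them), `different_chromosome` (a chimera candidate:
#' ends on different references), `wrong_orientation` (same reference but
#' both ends on the same strand), and `below_range` / `above_range`
#' (correct orientation but absolute separation outside the closed interval
#' `[min_distance, max_distance]`). Classification precedence is: unpaired,
#' different chromosome, wrong orientation, range check, good.
#'
#' An end is *usable* when it is mapped and (by default) maps uniquely —
#' the classification is based on unique genome hits; non-unique ends are
#' treated like unmapped ones. Pairs with no usable end are excluded
#' (`NA`).
#'
#' @param pairs A tibble with one row per pair and columns `ref1`,
#'   `strand1`, `start1`, `mapped1`, `unique1`, `ref2`, `strand2`,
#'   `start2`, `mapped2`, `unique2`.
#' @param config A [pair_config()] (or any list with `min_distance`,
#'   `max_distance`).
#' @param unique_only Require usable ends to be unique hits (default TRUE).
#' @return A factor of categories (levels as above), `NA` for pairs with no
#'   usable end.
#' @export
classify_pairs <- function(pairs, config, unique_only = TRUE) {
  min_d <- config$min_distance; max_d <- config$max_distance
  use1 <- pairs$mapped1 & (!unique_only | pairs$unique1)
  use2 <- pairs$mapped2 & (!unique_only | pairs$unique2)
  use1[is.na(use1)] <- FALSE
  use2[is.na(use2)] <- FALSE
  d <- abs(pair_distance(pairs$start1, pairs$start2))
  cat <- dplyr::case_when(
    !use1 & !use2 ~ NA_character_,
    use1 & !use2 ~ "unpaired_forward",
    !use1 & use2 ~ "unpaired_reverse",
    pairs$ref1 != pairs$ref2 ~ "different_chromosome",
    pairs$strand1 == pairs$strand2 ~ "wrong_orientation",
    d < min_d ~ "below_range",
    d > max_d ~ "above_range",
    TRUE ~ "good_pair"
  )
  factor(cat, levels = pair_category_levels)
}

#' @rdname classify_pairs
#' @param end1,end2 For the single-pair form: lists (or one-row data
#'   frames) with fields `reference`, `strand`, `start`, `mapped`,
#'   `unique`, or `NULL` for an end with no record.
#' @return `classify_pair()` returns a single character category (or `NA`).
#' @export
classify_pair <- function(end1, end2, config, unique_only = TRUE) {
  f <- function(e, what) {
    if (is.null(e)) return(switch(what, mapped = FALSE, unique = FALSE,
                                  reference = NA_character_,
                                  strand = NA_character_, start = NA_integer_))
    e[[what]] %||% NA
  }
  pairs <- tibble(
    ref1 = f(end1, "reference"), strand1 = f(end1, "strand"),
    start1 = f(end1, "start"), mapped1 = f(end1, "mapped"),
    unique1 = f(end1, "unique"),
    ref2 = f(end2, "reference"), strand2 = f(end2, "strand"),
    start2 = f(end2, "start"), mapped2 = f(end2, "mapped"),
    unique2 = f(end2, "unique"))
  as.character(classify_pairs(pairs, config, unique_only = unique_only))
}

#' Summarize paired-end/mate-pair library quality
#'
#' Classifies every pair in an alignment set (see [classify_pairs()]),
#' counts the six categories, reports the chimera fraction
#' (`different_chromosome` + `wrong_orientation` over classified pairs) and
#' builds the signed pair-distance histogram of good pairs, split by the
#' strand of the first end so strand bias in the library is visible.
#'
#' @param hits Alignment tibble from [read_sam()] containing both mates
#'   (flags 0x40/0x80), or a pre-built pair tibble as accepted by
#'   [classify_pairs()].
#' @param config A [pair_config()].
#' @param hist_bin Bin width (bp) of the distance histograms.
#' @param unique_only Classification based on unique genome hits (default).
#' @return An object of class `pair_summary`: list with `counts` (tibble
#'   `category`, `n`, all six categories always present), `n_pairs`
#'   (classified), `n_excluded` (no usable end), `chimera_fraction`,
#'   `distances` (tibble `bin_start`, `strand`, `n` for good pairs) and
#'   `config`.
#' @export
summarize_pairs <- function(hits, config, hist_bin = 100L, unique_only = TRUE) {
  if (all(c("ref1", "ref2", "start1", "start2") %in% names(hits))) {
    pairs <- hits
  } else {
    pairs <- pair_table(hits)
  }
  cat <- classify_pairs(pairs, config, unique_only = unique_only)
  counts <- tibble(category = pair_category_levels,
                   n = as.vector(table(cat)[pair_category_levels]))
  counts$n[is.na(counts$n)] <- 0L
  n_pairs <- sum(counts$n)
  chim <- sum(counts$n[counts$category %in%
                         c("different_chromosome", "wrong_orientation")])
  good <- !is.na(cat) & cat == "good_pair"
  d <- pair_distance(pairs$start1[good], pairs$start2[good])
  strand <- pairs$strand1[good]
  distances <- if (length(d)) {
    dplyr::count(tibble(bin_start = floor(d / hist_bin) * hist_bin,
                        strand = strand),
                 .data$bin_start, .data$strand, name = "n")
  } else {
    tibble(bin_start = numeric(), strand = character(), n = integer())
  }
  structure(list(counts = counts, n_pairs = n_pairs,
                 n_excluded = sum(is.na(cat)),
                 chimera_fraction = if (n_pairs > 0) chim / n_pairs else NA_real_,
                 distances = distances, hist_bin = hist_bin, config = config),
            class = "pair_summary")
}

# reshape per-record alignments into one row per pair (best hit per end)
pair_table <- function(hits) {
  ord <- order(paste(hits$read_id, hits$mate), !hits$mapped, hits$mismatches,
               na.last = TRUE)
  h <- hits[ord, ]
  h <- h[!duplicated(paste(h$read_id, h$mate)), ]
  e1 <- h[h$mate == "1", ]
  e2 <- h[h$mate == "2", ]
  ids <- union(e1$read_id, e2$read_id)
  i1 <- match(ids, e1$read_id); i2 <- match(ids, e2$read_id)
  tibble(
    read_id = ids,
    ref1 = e1$reference[i1], strand1 = e1$strand[i1], start1 = e1$start[i1],
    mapped1 = !is.na(i1) & e1$mapped[i1], unique1 = !is.na(i1) & e1$unique[i1],
    ref2 = e2$reference[i2], strand2 = e2$strand[i2], start2 = e2$start[i2],
    mapped2 = !is.na(i2) & e2$mapped[i2], unique2 = !is.na(i2) & e2$unique[i2])
}

#' @export
print.pair_summary <- function(x, ...) {
  cat(sprintf("<pair_summary> %d classified pairs (%d excluded), chimera fraction %.3f\n",
              x$n_pairs, x$n_excluded, x$chimera_fraction))
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("  %-22s %d\n", x$counts$category[i], x$counts$n[i]))
  }
  invisible(x)
}
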
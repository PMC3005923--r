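#' Read alignments from a SAM file
#'
#' Consumes aligner output as SAM (the upstream alignment stage is treated
#' as an external producer; any aligner emitting NM tags works). Mapped and
#' unmapped records are both returned: unmapped records carry `NA`
#' reference/position and participate only in pair accounting. Uniqueness is
#' aligner-tag-agnostic: an end is unique iff its (normalized) read id +
#' mate maps exactly once in the file, determined by a single-pass tally
#' over mapped records.
#'
#' Mapped records lacking an NM tag are kept with `NA` mismatches; they are
#' counted (attribute `n_missing_nm`) and excluded from mismatch-bucketed
#' tallies downstream. The MD tag, when present on an indel-free alignment,
#' supports the per-cycle mismatch mask used by [mismatch_rate_per_cycle()].
#'
#' @param path SAM file with header (`@SQ` lines required for mapped
#'   records).
#' @return A tibble with one row per alignment record: `read_id`
#'   (normalized), `mate` (`"1"`/`"2"`), `reference`, `start` (0-based),
#'   `strand`, `mapped`, `mismatches`, `md`, `cigar`, `read_length`,
#'   `unique`. Attributes: `targets` (named vector of reference lengths),
#'   `n_records`, `n_missing_nm`.
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "mapq", "cigar", "qwidth"),
    tag = c("NM", "MD"))
  b <- Rsamtools::scanBam(bam, param = param)[[1]]
  targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  flag <- b$flag
  mapped <- bitwAnd(flag, 4L) == 0L
  paired <- bitwAnd(flag, 1L) != 0L
  mate <- ifelse(paired & bitwAnd(flag, 128L) != 0L, "2", "1")
  out <- tibble(
    read_id = normalize_read_ids(b$qname),
    mate = mate,
    reference = as.character(b$rname),
    start = b$pos - 1L,
    strand = as.character(b$strand),
    mapped = mapped,
    mismatches = b$tag$NM,
    md = b$tag$MD,
    cigar = b$cigar,
    read_length = b$qwidth
  )
  out$strand[!mapped] <- NA_character_
  key <- paste(out$read_id, out$mate)
  hit_n <- table(key[mapped])
  out$unique <- mapped & as.vector(hit_n[key]) == 1L
  out$unique[!mapped] <- FALSE
  attr(out, "targets") <- targets
  attr(out, "n_records") <- nrow(out)
  attr(out, "n_missing_nm") <- sum(mapped & is.na(out$mismatches))
  out
}

# Positions (0-based, read-cycle order) of substitutions encoded by an MD
# tag on an indel-free alignment. MD runs in reference order; for a
# minus-strand alignment reference order is the reverse of cycle order.
md_mismatch_cycles <- function(md, strand, read_length) {
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1]]
  pos <- 0L
  hits <- integer()
  for (t in toks) {
    if (grepl("^[0-9]+$", t)) {
      pos <- pos + as.integer(t)
    } else if (startsWith(t, "^")) {
      return(NULL)  # deletion: mask undefined for this record
    } else {
      hits <- c(hits, pos)
      pos <- pos + 1L
    }
  }
  if (identical(strand, "-")) hits <- read_length - 1L - hits
  sort(hits)
}

# TRUE for alignments whose CIGAR is a single match run (no indels/clips)
is_simple_cigar <- function(cigar) {
  !is.na(cigar) & grepl("^[0-9]+M$", cigar)
}
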
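# fixture builders shared across test files; everything generated in code

tiny_layout <- function() flowcell_layout(2, 2, tile_x = 100, tile_y = 100)

# hand-rolled reads tibble (basespace), bypassing files
reads_tbl <- function(tile_id, x, y, symbols, quals = NULL, mate = "1") {
  n <- length(symbols)
  quals <- quals %||% strrep("I", nchar(symbols))
  out <- tibble::tibble(
    read_id = sprintf("R:1:FC:1:%s:%d:%d %s:N:0:ACGT", tile_id, x, y, mate),
    tile_id = as.character(tile_id), x = as.integer(x), y = as.integer(y),
    mate = mate, symbols = symbols, quals = quals)
  attr(out, "alphabet") <- "base"
  attr(out, "n_records") <- n
  attr(out, "n_coordless") <- 0L
  out
}

write_fastq_lines <- function(ids, seqs, quals, path) {
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

# minimal SAM writer: records is a character vector of body lines
write_sam <- function(records, path = tempfile(fileext = ".sam"),
                      targets = c(ref1 = 100000L)) {
  header <- c("@HD\tVN:1.6",
              sprintf("@SQ\tSN:%s\tLN:%d", names(targets), targets))
  writeLines(c(header, records), path)
  path
}

sam_rec <- function(qname, flag = 0L, rname = "ref1", pos = 1L, mapq = 60L,
                    cigar = "10M", seq = strrep("A", 10), qual = strrep("I", 10),
                    tags = "NM:i:0\tMD:Z:10") {
  if (bitwAnd(flag, 4L) > 0L) {
    sprintf("%s\t%d\t*\t0\t0\t*\t*\t0\t0\t%s\t%s", qname, flag, seq, qual)
  } else {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\t%s",
            qname, flag, rname, pos, mapq, cigar, seq, qual, tags)
  }
}

empty_reads_for_test <- function() {
  reads_tbl(character(), integer(), integer(), character())
}

# independent brute-force chi-square/df for unevenness (the oracle)
oracle_unevenness <- function(v) {
  v <- v[!is.na(v)]
  e <- sum(v) / length(v)
  sum((v - e)^2 / e) / (length(v) - 1)
}

# independent decision table for pair classification (nested rules written
# separately from the implementation)
oracle_classify <- function(m1, u1, ref1, s1, p1, m2, u2, ref2, s2, p2,
                            lo, hi) {
  ok1 <- m1 && u1
  ok2 <- m2 && u2
  if (!ok1 && !ok2) return(NA_character_)
  if (ok1 && !ok2) return("unpaired_forward")
  if (!ok1 && ok2) return("unpaired_reverse")
  if (ref1 != ref2) return("different_chromosome")
  if (s1 == s2) return("wrong_orientation")
  d <- abs(p1 - p2)
  if (d < lo) return("below_range")
  if (d > hi) return("above_range")
  "good_pair"
}
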
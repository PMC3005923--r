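test_that("read-id dialects recover tile, x, y and mate", {
  r <- parse_read_ids("HWUSI-EAS100R:6:73:941:1973#0/1")
  expect_equal(r$tile_id, "73")
  expect_equal(r$x, 941L)
  expect_equal(r$y, 1973L)
  expect_equal(r$mate, "1")

  r <- parse_read_ids("M1:RUN:FC:1:1101:5:7 1:N:0:ACGT")
  expect_equal(unlist(r[c("tile_id", "x", "y", "mate")], use.names = FALSE),
               c("1101", 5L, 7L, "1"))

  r <- parse_read_ids(c(">1_52_85_F3", ">429_1003_22_R3", ">1_52"))
  expect_equal(r$tile_id[1:2], c("1", "429"))
  expect_equal(r$x[1:2], c(52L, 1003L))
  expect_equal(r$y[1:2], c(85L, 22L))
  expect_equal(r$mate[1:2], c("F3", "R3"))
  expect_false(r$ok[3])          # coordinate-less, not a crash

  expect_false(parse_read_ids("noCoordsHere")$ok)
})

test_that("generated read ids round-trip in every dialect", {
  lay <- layout_mini()
  for (d in c("casava18", "legacy", "solid")) {
    alpha <- if (d == "solid") "color" else "base"
    sim <- simulate_flowcell(lay, n_reads = 400, read_length = 8,
                             alphabet = alpha, seed = 31, dialect = d)
    p <- parse_read_ids(sim$reads$read_id, dialect = d)
    expect_true(all(p$ok), info = d)
    expect_identical(p$tile_id, sim$reads$tile_id)
    expect_identical(p$x, sim$reads$x)
    expect_identical(p$y, sim$reads$y)
  }
})

test_that("id normalization collapses mate/index/tag suffixes", {
  expect_equal(normalize_read_ids(c("r7/1", "r7/2", "@r7#0/1", ">12_4_8_F3",
                                    "a:b:1:2:3 1:N:0:ACGT")),
               c("r7", "r7", "r7", "12_4_8", "a:b:1:2:3"))
})

test_that("FASTQ reader parses records, detects encodings, counts errors", {
  lay <- tiny_layout()
  fq <- tempfile(fileext = ".fastq")
  write_fastq_lines(c("R:1:FC:1:1:5:7 1:N:0:ACGT", "R:1:FC:1:2:8:9 1:N:0:ACGT"),
                    c("ACGTN", "TTTTT"), c("III#I", "IIIII"), fq)
  r <- read_fastq(fq, lay)
  expect_equal(nrow(r), 2L)
  expect_equal(attr(r, "n_records"), 2L)
  expect_equal(attr(r, "n_coordless"), 0L)
  expect_equal(r$symbols, c("ACGTN", "TTTTT"))
  expect_equal(attr(r, "qual_offset"), 33L)

  # Phred+64 range forces offset 64 and re-encoding to +33
  fq64 <- tempfile(fileext = ".fastq")
  write_fastq_lines("R:1:FC:1:1:5:7 1:N:0:ACGT", "ACGT", "hhhh", fq64)
  r64 <- read_fastq(fq64, lay)
  expect_equal(attr(r64, "qual_offset"), 64L)
  expect_equal(utf8ToInt(r64$quals) - 33L, rep(40L, 4L))  # 'h' under +64 is Q40

  # truncated file is a hard error naming the line region
  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@x", "ACGT", "+"), bad)
  expect_error(read_fastq(bad, lay), "truncated")

  # empty file: empty stream plus a warning
  empty <- tempfile(fileext = ".fastq")
  file.create(empty)
  expect_warning(re <- read_fastq(empty, lay), "empty")
  expect_equal(nrow(re), 0L)
})

test_that("FASTQ conservation: records in == rows out + counted errors", {
  lay <- tiny_layout()
  fq <- tempfile(fileext = ".fastq")
  ids <- c("R:1:FC:1:1:5:7 1:N:0:ACGT", "R:1:FC:1:1:6:8 1:N:0:ACGT",
           "R:1:FC:1:9:1:1 1:N:0:ACGT",   # unknown tile
           "R:1:FC:1:2:5:500 1:N:0:ACGT") # out of tile bounds after shift
  write_fastq_lines(ids, rep("ACGT", 4), rep("II#I", 4), fq)
  r <- read_fastq(fq, lay)
  expect_equal(nrow(r), attr(r, "n_records"))
  expect_equal(attr(r, "n_unknown_tile"), 1L)
  expect_equal(attr(r, "n_out_of_bounds"), 1L)
  expect_equal(sum(!is.na(r$tile_id)) + attr(r, "n_unknown_tile"), 4L)
})

test_that("csfasta/qual pairing is strict and colorspace conventions hold", {
  cf <- tempfile(fileext = ".csfasta"); qf <- tempfile(fileext = ".qual")
  writeLines(c("# comment", ">1_52_85_F3", "T0123.01",
               ">2_10_20_F3", "T3210032"), cf)
  writeLines(c("# comment", ">1_52_85_F3", "20 21 22 23 4 25 26",
               ">2_10_20_F3", "9 9 9 9 9 9 9"), qf)
  lay <- flowcell_layout(1, 2, 100, 100)
  r <- read_csfasta(cf, qf, lay)
  expect_equal(nrow(r), 2L)
  expect_equal(r$symbols[1], "0123.01")        # primer stripped from symbols
  expect_equal(attr(r, "primers")[1], "T")     # but retained as metadata
  expect_equal(nchar(r$quals[1]), 7L)          # one qual per color call
  expect_equal(attr(r, "alphabet"), "color")

  # count mismatch: hard error
  qf2 <- tempfile(fileext = ".qual")
  writeLines(c(">1_52_85_F3", "20 21 22 23 4 25 26"), qf2)
  expect_error(read_csfasta(cf, qf2, lay), "mismatch")

  # diverging headers: hard error naming the first divergence
  qf3 <- tempfile(fileext = ".qual")
  writeLines(c(">1_52_85_F3", "20 21 22 23 4 25 26",
               ">9_9_9_F3", "9 9 9 9 9 9 9"), qf3)
  expect_error(read_csfasta(cf, qf3, lay), "diverge.*9_9_9_F3")
})

test_that("colorspace and basespace streams are structurally identical", {
  lay <- layout_mini()
  d1 <- tempfile(); d2 <- tempfile()
  sb <- simulate_flowcell(lay, 300, read_length = 10, alphabet = "base",
                          seed = 5, dir = d1)
  sc <- simulate_flowcell(lay, 300, read_length = 10, alphabet = "color",
                          seed = 5, dir = d2)
  rb <- read_fastq(sb$files["reads"], lay)
  rc <- read_csfasta(sc$files["csfasta"], sc$files["qual"], lay)
  expect_identical(names(rb), names(rc))
  expect_identical(dim(rb), dim(rc))
  expect_identical(rb$tile_id, rc$tile_id)
  expect_identical(rb$x, rc$x)
  expect_identical(rb$y, rc$y)
})

test_that("layout files parse, validate and round-trip", {
  p <- tempfile()
  writeLines(c("platform: demo", "rows: 3", "cols: 2",
               "tile_x: 1000", "tile_y: 2000",
               "0 0 a", "0 1 b", "1 0 c", "1 1 d", "2 0 e", "2 1 f"), p)
  lay <- parse_layout_file(p)
  expect_equal(nrow(lay$tiles), 6L)
  expect_equal(lay$tiles$row, rep(0:2, each = 2))
  expect_equal(lay$tiles$col, rep(0:1, times = 3))
  expect_false(any(lay$tiles$unused))

  # unused corner marks carry the missing-data flag through sample matrices
  p2 <- tempfile()
  write_layout_file(layout_slide_mini(), p2)
  lay2 <- parse_layout_file(p2)
  expect_equal(sum(lay2$tiles$unused), 4L)
  tm <- tile_metrics(empty_reads_for_test(), lay2)
  sg <- sample_matrix(tm, "read_count")
  expect_true(all(sg$missing[sg$tile_id %in%
                               lay2$tiles$tile_id[lay2$tiles$unused]]))

  # duplicate tile id / bad extents / malformed lines are hard errors
  bad <- tempfile()
  writeLines(c("platform: x", "rows: 1", "cols: 2", "tile_x: 10", "tile_y: 10",
               "0 0 t1", "0 1 t1"), bad)
  expect_error(parse_layout_file(bad), "duplicate tile_id")
  bad2 <- tempfile()
  writeLines(c("platform: x", "rows: 1", "cols: 1", "tile_x: 0", "tile_y: 10",
               "0 0 t1"), bad2)
  expect_error(parse_layout_file(bad2), "positive")
  bad3 <- tempfile()
  writeLines(c("platform: x", "rows: 1", "cols: 1", "tile_x: 10", "tile_y: 10",
               "zero zero t1"), bad3)
  expect_error(parse_layout_file(bad3), "malformed")
})

test_that("pair configuration files follow the two-line contract", {
  p <- tempfile()
  writeLines(c("pair: end1.fq end2.fq", "range: 500 5000"), p)
  cfg <- parse_pair_config(p)
  expect_equal(cfg$end1_file, "end1.fq")
  expect_equal(cfg$end2_file, "end2.fq")
  expect_equal(cfg$min_distance, 500L)
  expect_equal(cfg$max_distance, 5000L)

  rev <- tempfile(); writeLines(c("pair: a b", "range: 5000 500"), rev)
  expect_error(parse_pair_config(rev), "min < max")
  noline <- tempfile(); writeLines("pair: a b", noline)
  expect_error(parse_pair_config(noline), "range")
})

test_that("SAM reader derives uniqueness, strands and tags", {
  sam <- write_sam(c(
    sam_rec("u1", 0L, pos = 100L, tags = "NM:i:2\tMD:Z:2A3C3"),
    sam_rec("m1", 0L, pos = 200L, mapq = 0L),
    sam_rec("m1", 256L, pos = 300L, mapq = 0L, seq = "*", qual = "*"),
    sam_rec("nonm", 16L, pos = 400L, tags = "MD:Z:10"),
    sam_rec("un1", 4L)))
  h <- read_sam(sam)
  expect_equal(attr(h, "n_records"), 5L)
  expect_equal(attr(h, "targets"), c(ref1 = 100000L))
  u1 <- h[h$read_id == "u1", ]
  expect_true(u1$unique)
  expect_equal(u1$mismatches, 2L)
  expect_equal(u1$start, 99L)               # 0-based
  expect_false(any(h$unique[h$read_id == "m1"]))  # two mapped records
  expect_equal(attr(h, "n_missing_nm"), 1L)
  un <- h[h$read_id == "un1", ]
  expect_false(un$mapped)
  expect_true(is.na(un$reference))
})

test_that("read-id lists normalize, deduplicate and reject empties", {
  p <- tempfile()
  writeLines(c("r1/1", "r2", "r1/2", ""), p)
  expect_message(ids <- load_id_list(p), "1 duplicate")
  expect_setequal(ids, c("r1", "r2"))
  expect_equal(attr(ids, "n_duplicates"), 1L)

  blank <- tempfile(); writeLines(c("", "   "), blank)
  expect_error(load_id_list(blank), "empty")
})
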
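test_that("hit tallies collapse multi-hits and bucket by best mismatch", {
  lay <- tiny_layout()
  reads <- reads_tbl(c("1", "1", "2"), x = c(1L, 2L, 3L), y = c(1L, 2L, 3L),
                     symbols = rep(strrep("A", 10), 3))
  rid <- normalize_read_ids(reads$read_id)
  sam <- write_sam(c(
    sam_rec(rid[1], 0L, pos = 10L, tags = "NM:i:0\tMD:Z:10"),
    sam_rec(rid[2], 0L, pos = 50L, mapq = 0L, tags = "NM:i:2\tMD:Z:1A1A7"),
    sam_rec(rid[2], 256L, pos = 90L, mapq = 0L, seq = "*", qual = "*",
            tags = "NM:i:4\tMD:Z:0A0A0A0A6"),
    sam_rec(rid[2], 256L, pos = 95L, mapq = 0L, seq = "*", qual = "*",
            tags = "NM:i:3\tMD:Z:0A0A0A7"),
    sam_rec(rid[3], 4L)))
  tally <- tally_hits(read_sam(sam), reads, lay)
  bt <- tally$by_tile
  expect_equal(bt$n[bt$tile_id == "1" & bt$bucket == "0" &
                      bt$uniqueness == "unique"], 1L)
  # three hits collapse to one 'multiple' outcome at the best NM (2)
  expect_equal(bt$n[bt$tile_id == "1" & bt$bucket == "2" &
                      bt$uniqueness == "multiple"], 1L)
  expect_equal(sum(bt$n), 2L)
  expect_equal(sum(tally$unmapped$n), 1L)
  expect_equal(tally$n_unlocatable, 0L)
  # a hit with no surface coordinate is counted, not dropped
  sam2 <- write_sam(sam_rec("ghost", 0L))
  t2 <- tally_hits(read_sam(sam2), reads, lay)
  expect_equal(t2$n_unlocatable, 1L)
})

test_that("a low-mappability tile band matches generator truth exactly", {
  lay <- layout_mini()
  sim <- simulate_flowcell(lay, n_reads = 8000, read_length = 10, seed = 61)
  band <- lay$tiles$tile_id[lay$tiles$row == 0]          # top row of the chip
  mp <- setNames(rep(1, nrow(lay$tiles)), lay$tiles$tile_id)
  mp[band] <- 0.6
  al <- simulate_alignments(sim, per_cycle_rate = 0, tile_mappability = mp,
                            seed = 62)
  tally <- tally_hits(read_sam(al$sam), sim$reads, lay)
  got <- dplyr::summarise(dplyr::group_by(tally$by_tile, tile_id),
                          n = sum(n), .groups = "drop")
  expect_equal(setNames(got$n, got$tile_id)[names(al$truth$tile_mapped)],
               al$truth$tile_mapped)
  # the band is visibly depleted in the hit-count sample grid
  tm <- tile_metrics(sim$reads, lay)
  hg <- sample_matrix(tm, "hit_count", tally = tally)
  expect_lt(max(hg$value[hg$tile_id %in% band]),
            min(hg$value[!(hg$tile_id %in% band)]))
})

test_that("per-cycle mismatch rates recover injected substitution profiles", {
  lay <- tiny_layout()
  # error-free alignments: an all-zero vector
  sim0 <- simulate_flowcell(lay, n_reads = 500, read_length = 12, seed = 71)
  al0 <- simulate_alignments(sim0, per_cycle_rate = 0, seed = 72)
  mr0 <- mismatch_rate_per_cycle(read_sam(al0$sam))
  expect_equal(mr0$rate, rep(0, 12))

  # rising profile 0.01 * (1 + c/L), recovered within 3 binomial SD
  L <- 20L
  sim <- simulate_flowcell(layout_mini(), n_reads = 20000, read_length = L,
                           seed = 73)
  al <- simulate_alignments(sim, per_cycle_rate = function(c, L) 0.01 * (1 + c / L),
                            seed = 74)
  mr <- mismatch_rate_per_cycle(read_sam(al$sam))
  truth <- 0.01 * (1 + seq_len(L) / L)
  z <- abs(mr$rate - truth) / sqrt(truth * (1 - truth) / mr$n_reads)
  expect_true(all(z < 3))

  # single read with mismatches at cycles 3 and 7 (plus and minus strand)
  reads <- reads_tbl("1", x = 1L, y = 1L, symbols = strrep("A", 10))
  rid <- normalize_read_ids(reads$read_id)
  for (rec in list(
    sam_rec(rid, 0L, tags = "NM:i:2\tMD:Z:2C3C3"),
    sam_rec(rid, 16L, tags = "NM:i:2\tMD:Z:3G3G2"))) {  # ref order flipped
    mr1 <- mismatch_rate_per_cycle(read_sam(write_sam(rec)))
    expect_equal(mr1$rate, as.numeric(seq_len(10) %in% c(3, 7)))
  }
})

test_that("NM tags always equal the injected mask popcount", {
  sim <- simulate_flowcell(layout_mini(), n_reads = 600, read_length = 15,
                           seed = 81)
  al <- simulate_alignments(sim, per_cycle_rate = 0.05, seed = 82)
  h <- read_sam(al$sam)
  h <- h[h$mapped, ]
  masks <- mapply(function(md, s, l) {
    length(seqtileqc:::md_mismatch_cycles(md, s, l))
  }, h$md, h$strand, h$read_length)
  expect_equal(unname(masks), h$mismatches)
})

test_that("target histograms conserve counts and flag unknown references", {
  # 10 reads all starting within the first bin
  recs <- vapply(1:10, function(i) sam_rec(sprintf("r%02d", i), 0L,
                                           pos = i * 3L), character(1))
  h <- read_sam(write_sam(recs, targets = c(ref1 = 1000L)))
  th <- target_hit_histogram(h, bin_size = 100L)
  expect_equal(th$count[1], 10L)
  expect_equal(sum(th$count), 10L)
  expect_equal(nrow(th), 10L)   # 1000/100 bins, zeros included
  expect_error(target_hit_histogram(h, 100L, reference_lengths = c(chrX = 50L)),
               "absent")

  # uniform starts stay within 5 sqrt(expected) of the expectation
  sim <- simulate_flowcell(layout_mini(), n_reads = 20000, read_length = 10,
                           seed = 91)
  al <- simulate_alignments(sim, reference_length = 1e6, seed = 92)
  th2 <- target_hit_histogram(read_sam(al$sam), bin_size = 1e5)
  expected <- sum(th2$count) / nrow(th2)
  expect_true(all(abs(th2$count - expected) <= 5 * sqrt(expected)))
  expect_equal(sum(th2$count), al$truth$n_mapped)
})

test_that("hit-count deficit outranks composition deviation as a defect signal", {
  # severity grows with the tile column: mappability falls steeply while
  # composition drifts by only a small gradient
  lay <- layout_mini()
  sim <- simulate_flowcell(lay, n_reads = 15000, read_length = 10, seed = 101,
                           effects = flowcell_effects(gradient_symbol = "A",
                                                      gradient_amplitude = 0.01))
  severity <- (lay$tiles$col + 0.5) / lay$cols
  mp <- setNames(1 - 0.5 * severity, lay$tiles$tile_id)
  al <- simulate_alignments(sim, tile_mappability = mp, seed = 102)
  tm <- tile_metrics(sim$reads, lay)
  tally <- tally_hits(read_sam(al$sam), sim$reads, lay)
  hit_rate <- sample_matrix(tm, "hit_count", tally = tally)$value /
    sample_matrix(tm, "read_count")$value
  comp <- sample_matrix(tm, "symbol_fraction", symbol = "A")$value
  cor_hit <- abs(cor(severity, hit_rate, method = "spearman"))
  cor_comp <- abs(cor(severity, comp, method = "spearman"))
  expect_gt(cor_hit, cor_comp)
})
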
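cfg <- pair_config(min_distance = 500, max_distance = 5000)

end <- function(ref = "chr1", strand = "+", start = 1000L,
                mapped = TRUE, unique = TRUE) {
  list(reference = ref, strand = strand, start = start,
       mapped = mapped, unique = unique)
}

test_that("pair distance is signed and antisymmetric", {
  expect_equal(pair_distance(100, 600), -500)
  expect_equal(pair_distance(5000, 100), 4900)
  expect_equal(pair_distance(7, 7), 0)
  set.seed(5)
  a <- sample.int(1e6, 50); b <- sample.int(1e6, 50)
  expect_equal(pair_distance(a, b), -pair_distance(b, a))
})

test_that("single pairs classify by the documented precedence", {
  expect_equal(classify_pair(end("chr1", "+", 1000), end("chr1", "-", 2500), cfg),
               "good_pair")
  expect_equal(classify_pair(end("chr1"), end("chr7", "-"), cfg),
               "different_chromosome")
  expect_equal(classify_pair(end("chr1", "+", 1000), end("chr1", "+", 2500), cfg),
               "wrong_orientation")
  expect_equal(classify_pair(end("chr1", "+", 1000), end("chr1", "-", 1200), cfg),
               "below_range")
  expect_equal(classify_pair(end("chr1", "+", 1000), end("chr1", "-", 7000), cfg),
               "above_range")
  # closed interval: |d| exactly at either bound is still good
  expect_equal(classify_pair(end("chr1", "+", 1000), end("chr1", "-", 1500), cfg),
               "good_pair")
  expect_equal(classify_pair(end("chr1", "+", 1000), end("chr1", "-", 6000), cfg),
               "good_pair")
  # orphan ends split by which end survived
  expect_equal(classify_pair(end(), end(mapped = FALSE), cfg), "unpaired_forward")
  expect_equal(classify_pair(end(mapped = FALSE), end(), cfg), "unpaired_reverse")
  # a non-unique end counts as unusable under unique-hit classification
  expect_equal(classify_pair(end(unique = FALSE), end(), cfg), "unpaired_reverse")
  expect_true(is.na(classify_pair(end(mapped = FALSE), end(mapped = FALSE), cfg)))
})

test_that("classification agrees with the brute-force decision table", {
  grid <- expand.grid(
    m1 = c(TRUE, FALSE), u1 = c(TRUE, FALSE),
    ref1 = c("chr1", "chr2"), s1 = c("+", "-"),
    off = c(-6000L, -1000L, 0L, 200L, 1000L, 6000L),
    m2 = c(TRUE, FALSE), u2 = c(TRUE, FALSE),
    ref2 = c("chr1", "chr2"), s2 = c("+", "-"),
    stringsAsFactors = FALSE)
  p2 <- 10000L
  got <- classify_pairs(
    tibble::tibble(ref1 = grid$ref1, strand1 = grid$s1, start1 = p2 + grid$off,
                   mapped1 = grid$m1, unique1 = grid$u1,
                   ref2 = grid$ref2, strand2 = grid$s2, start2 = p2,
                   mapped2 = grid$m2, unique2 = grid$u2),
    cfg)
  want <- mapply(oracle_classify, grid$m1, grid$u1, grid$ref1, grid$s1,
                 p2 + grid$off, grid$m2, grid$u2, grid$ref2, grid$s2, p2,
                 MoreArgs = list(lo = 500, hi = 5000))
  expect_equal(as.character(got), unname(want))
  expect_gt(nrow(grid), 1500)   # full enumeration, not a sample
})

test_that("every processed pair lands in exactly one category", {
  set.seed(13)
  n <- 400
  pairs <- tibble::tibble(
    ref1 = sample(c("chr1", "chr2"), n, TRUE), strand1 = sample(c("+", "-"), n, TRUE),
    start1 = sample.int(1e5, n), mapped1 = runif(n) < 0.8, unique1 = runif(n) < 0.9,
    ref2 = sample(c("chr1", "chr2"), n, TRUE), strand2 = sample(c("+", "-"), n, TRUE),
    start2 = sample.int(1e5, n), mapped2 = runif(n) < 0.8, unique2 = runif(n) < 0.9)
  cat <- classify_pairs(pairs, cfg)
  s <- summarize_pairs(pairs, cfg)
  expect_equal(s$n_pairs + s$n_excluded, n)
  expect_equal(sum(s$counts$n), sum(!is.na(cat)))
})

test_that("generated pair sets reproduce their category counts exactly", {
  counts <- c(good_pair = 70, different_chromosome = 10, wrong_orientation = 5,
              below_range = 8, above_range = 7, unpaired_forward = 6,
              unpaired_reverse = 4)
  ps <- simulate_pairs(counts, cfg, seed = 19)
  s <- summarize_pairs(read_sam(ps$sam), cfg)
  expect_equal(setNames(s$counts$n, s$counts$category)[names(counts)], counts)
  expect_equal(s$chimera_fraction, 15 / 110)

  # degenerate case: only good pairs
  ps2 <- simulate_pairs(c(good_pair = 10), cfg, seed = 20)
  s2 <- summarize_pairs(read_sam(ps2$sam), cfg)
  expect_equal(s2$counts$n, c(10L, 0L, 0L, 0L, 0L, 0L, 0L))
})

test_that("good-pair distances follow the truncated insert distribution", {
  ps <- simulate_pairs(c(good_pair = 2000), cfg, insert_mean = 2000,
                       insert_sd = 300, seed = 23)
  s <- summarize_pairs(read_sam(ps$sam), cfg, hist_bin = 50)
  d <- rep(abs(s$distances$bin_start) + 25, s$distances$n)
  expect_lt(abs(mean(d) - 2000), 3 * 300 / sqrt(2000) + 25)
  # symmetric strand assignment: plus/minus totals agree within 5 binomial SD
  tot <- tapply(s$distances$n, s$distances$strand, sum)
  expect_lt(abs(tot[["+"]] - tot[["-"]]), 5 * sqrt(2000 * 0.25) * 2)
  # the sign of the distance tracks the first-end strand
  plus <- s$distances[s$distances$strand == "+", ]
  expect_true(all(plus$bin_start < 0))
})
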
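test_that("tile accumulation handles pure, empty and uniform tiles", {
  lay <- tiny_layout()
  # 100 all-'A' reads on one tile: A-fraction 1.0 in every non-empty cell
  r <- reads_tbl("1", x = rep(0:9, 10), y = rep(0:9, each = 10),
                 symbols = rep("AAAA", 100))
  tm <- tile_metrics(r, lay, grid_resolution = c(2, 2))
  m <- spatial_composition_map(tm, "A", tile_id = "1")
  expect_true(all(m$fraction[m$n_called > 0] == 1))
  # a layout tile with no reads is present with read_count 0, all-missing cells
  expect_equal(tm$tiles$read_count[tm$tiles$tile_id == "4"], 0L)
  m4 <- spatial_composition_map(tm, "A", tile_id = "4")
  expect_true(all(is.na(m4$fraction)))
  # unknown symbol is a hard error
  expect_error(spatial_composition_map(tm, "Z"), "not in alphabet")
})

test_that("uniform reads give binomially flat composition", {
  lay <- layout_mini()
  sim <- simulate_flowcell(lay, n_reads = 10000, read_length = 20, seed = 17,
                           effects = flowcell_effects(no_call_rate = 0))
  tm <- tile_metrics(sim$reads, lay)
  cc <- cycle_composition(tm, "sample")
  a <- dplyr::filter(cc, symbol == "A")
  sd5 <- 5 * sqrt(0.25 * 0.75 / a$n_called)
  expect_true(all(abs(a$fraction - 0.25) < sd5))
  # per cycle, fractions over called symbols sum to 1
  sums <- dplyr::summarise(dplyr::group_by(cc, cycle), s = sum(fraction))
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("composition fractions use called symbols only", {
  lay <- tiny_layout()
  # one grid cell with A=30, C=10, G=5, T=5 called + 2 no-calls -> A 30/50
  syms <- c(rep("A", 30), rep("C", 10), rep("G", 5), rep("T", 5), rep("N", 2))
  r <- reads_tbl("1", x = seq_along(syms), y = rep(1L, length(syms)),
                 symbols = syms)
  tm <- tile_metrics(r, lay, grid_resolution = c(1, 1))
  m <- spatial_composition_map(tm, "A", tile_id = "1")
  expect_equal(m$fraction, 0.6)
  expect_equal(m$n_called, 50)
})

test_that("single-read scope yields 0/1 indicator fractions", {
  lay <- tiny_layout()
  r <- reads_tbl("1", x = 1L, y = 1L, symbols = "ACGT")
  tm <- tile_metrics(r, lay)
  cc <- cycle_composition(tm, "tile")
  cc1 <- dplyr::filter(cc, group == "1")
  expect_true(all(cc1$fraction %in% c(0, 1)))
  expect_equal(dplyr::filter(cc1, cycle == 1, symbol == "A")$fraction, 1)
})

test_that("injected spatial gradient is recovered across columns", {
  lay <- layout_mini()
  sim <- simulate_flowcell(lay, n_reads = 30000, read_length = 20, seed = 23,
                           effects = flowcell_effects(gradient_symbol = "A",
                                                      gradient_amplitude = 0.05,
                                                      no_call_rate = 0))
  tm <- tile_metrics(sim$reads, lay)
  g <- composition_gradient(tm, "A")
  expect_gt(g$rank_correlation, 0.9)
  expect_lt(abs(g$slope - 0.05), 0.01)
})

test_that("cyclic composition bias appears at exactly the injected cycles", {
  lay <- layout_mini()
  sim <- simulate_flowcell(lay, n_reads = 20000, read_length = 20,
                           alphabet = "color", seed = 29,
                           effects = flowcell_effects(cycle_symbol = "0",
                                                      cycle_period = 5L,
                                                      cycle_amplitude = 0.05,
                                                      no_call_rate = 0))
  tm <- tile_metrics(sim$reads, lay)
  cc <- dplyr::filter(cycle_composition(tm, "sample"), symbol == "0")
  biased <- cc$cycle %% 5L == 0L
  # every biased cycle sticks out above every unbiased cycle
  expect_gt(min(cc$fraction[biased]), max(cc$fraction[!biased]))
  amp <- mean(cc$fraction[biased]) - mean(cc$fraction[!biased])
  expect_lt(abs(amp - 0.05), 0.015)
})

test_that("stacking tiles is count-weighted and conserves symbol counts", {
  lay <- tiny_layout()
  r1 <- reads_tbl("1", x = c(1L, 60L), y = c(1L, 60L), symbols = c("AA", "CC"))
  r2 <- reads_tbl("2", x = c(1L, 60L), y = c(1L, 60L), symbols = c("AA", "CC"))
  both <- dplyr::bind_rows(r1, r2)
  attr(both, "alphabet") <- "base"
  tm1 <- tile_metrics(r1, lay, c(2, 2))
  tmb <- tile_metrics(both, lay, c(2, 2))
  s1 <- stack_tiles_xy(tm1, "read_density")
  sb <- stack_tiles_xy(tmb, "read_density")
  # two identical tiles stack to twice one tile, same shape
  expect_equal(sb$value, 2 * s1$value)
  # stacked symbol fraction reproduces the pooled counts, cell-wise
  sf <- stack_tiles_xy(tmb, "symbol_fraction", symbol = "A")
  pooled_a <- as.vector(colSums(tmb$cell_sym[, , "A"]))
  pooled_called <- as.vector(colSums(tmb$cell_called))
  expect_equal(ifelse(pooled_called > 0, sf$value * pooled_called, 0), pooled_a)
})

test_that("a repeated donut deficit shows in the stacked map, not per tile", {
  lay <- flowcell_layout(5, 8, 500, 500)   # 40 tiles
  mask <- matrix(1, 10, 10)
  donut <- cbind(rep(4:6, 3), rep(4:6, each = 3))
  mask[donut] <- 0.35
  sim <- simulate_flowcell(lay, n_reads = 40 * 400, read_length = 6, seed = 41,
                           effects = flowcell_effects(density_mask = mask))
  tm <- tile_metrics(sim$reads, lay, grid_resolution = c(10, 10))
  st <- stack_tiles_xy(tm, "read_density")
  donut_cells <- st$gx %in% 3:5 & st$gy %in% 3:5
  med <- stats::median(st$value[!donut_cells])
  expect_true(all(st$value[donut_cells] < 0.5 * med))
})

test_that("sample matrices carry exact values, missing flags and scales", {
  lay <- tiny_layout()
  r <- reads_tbl(c("1", "1", "2"), x = c(1L, 2L, 3L), y = c(1L, 2L, 3L),
                 symbols = rep("ACGT", 3), quals = rep("????", 3))  # Q30
  tm <- tile_metrics(r, lay)
  q <- sample_matrix(tm, "mean_quality")
  expect_equal(q$value[q$tile_id %in% c("1", "2")], c(30, 30))
  expect_true(all(q$missing[q$tile_id %in% c("3", "4")]))
  rc <- sample_matrix(tm, "read_count")
  expect_equal(attr(rc, "scale"), range(rc$value[!rc$missing]))
  expect_equal(attr(rc, "scale"), c(0, 2))
})

test_that("per-tile read counts stay within 5 SD of the expected depth", {
  lay <- layout_mini()
  n <- 20000L
  sim <- simulate_flowcell(lay, n_reads = n, read_length = 6, seed = 53)
  rc <- sample_matrix(tile_metrics(sim$reads, lay), "read_count")
  lambda <- n / nrow(lay$tiles)
  expect_true(all(abs(rc$value - lambda) <= 5 * sqrt(lambda)))
})

test_that("unevenness score matches hand-computed chi-square values", {
  expect_equal(unevenness_score(c(25, 25, 25, 25)), 0)
  # chi-square of (100,0,0,0) against e=25: (75^2 + 3*25^2)/25 = 300; /3 = 100
  expect_equal(unevenness_score(c(100, 0, 0, 0)), 100)
  expect_warning(s <- unevenness_score(c(0, 0)), "zero")
  expect_true(is.na(s))
  expect_warning(unevenness_score(numeric(0)), "fewer than 2")
})

test_that("unevenness equals the brute-force chi-square on random matrices", {
  set.seed(71)
  for (i in 1:200) {
    k <- sample(2:50, 1)
    v <- rpois(k, sample(1:50, 1)) + 1
    expect_equal(unevenness_score(v), oracle_unevenness(v), tolerance = 1e-12)
  }
})

test_that("unevenness has mean ~1 under multinomial-uniform counts", {
  set.seed(97)
  scores <- replicate(200, unevenness_score(as.vector(
    stats::rmultinom(1, 10000, rep(1, 100)))))
  se <- stats::sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores) - 1), 3 * se)
})

test_that("tiles rank by unevenness with deterministic tie-breaks", {
  lay <- layout_mini()
  # a half-empty tile among flat ones must rank first
  cliff <- matrix(1, 10, 10); cliff[1:5, ] <- 0
  hits_first <- 0L
  for (s in 1:25) {
    sim <- simulate_flowcell(lay, n_reads = 6000, read_length = 4, seed = 100 + s,
                             effects = flowcell_effects(
                               tile_density_mask = list(`13` = cliff)))
    tm <- tile_metrics(sim$reads, lay, grid_resolution = c(10, 10))
    rk <- rank_tiles_by_unevenness(tm, "read_count")
    hits_first <- hits_first + (rk$tile_id[1] == "13")
  }
  expect_gte(hits_first, 24L)  # >= 95% of replicates

  # all-identical tiles: equal scores, lexicographic order, flagged empties last
  r <- reads_tbl(c("1", "2", "3"), x = c(1L, 1L, 1L), y = c(1L, 1L, 1L),
                 symbols = rep("AC", 3))
  tmh <- tile_metrics(r, tiny_layout(), c(1, 2))
  rk2 <- rank_tiles_by_unevenness(tmh, "read_count")
  expect_equal(rk2$tile_id, c("1", "2", "3", "4"))
  expect_true(rk2$flagged[4])
})

test_that("cycle composition pools per-tile counts exactly (recomputed raw)", {
  lay <- tiny_layout()
  set.seed(7)
  syms <- replicate(60, paste(sample(c("A", "C", "G", "T", "N"), 5, TRUE,
                                     prob = c(.3, .3, .2, .15, .05)),
                              collapse = ""))
  r <- reads_tbl(sample(c("1", "2", "3"), 60, TRUE),
                 x = sample(0:99, 60, TRUE), y = sample(0:99, 60, TRUE),
                 symbols = syms)
  tm <- tile_metrics(r, lay)
  cc <- cycle_composition(tm, "sample")
  # oracle: recompute from the raw strings
  chars <- do.call(rbind, strsplit(r$symbols, ""))
  for (cy in 1:5) {
    called <- sum(chars[, cy] != "N")
    for (sym in c("A", "C", "G", "T")) {
      got <- dplyr::filter(cc, cycle == cy, symbol == sym)$fraction
      expect_equal(got, sum(chars[, cy] == sym) / called)
    }
  }
  # count conservation cell -> tile -> sample
  expect_equal(sum(tm$cell_reads), sum(tm$tiles$read_count))
  expect_equal(rowSums(tm$cell_reads), tm$tiles$read_count + 0,
               ignore_attr = TRUE)
  expect_equal(sum(tm$cyc_counts[, 1, ]), nrow(r))
})
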
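#' Describe the biases injected into a simulated flowcell
#'
#' The simulator emulates the quality problems the QC metrics are built to
#' detect, each as a stylized parametric effect:
#'
#' * `gradient_symbol`/`gradient_amplitude` — a left-to-right composition
#'   gradient across the chip: the biased symbol's probability rises
#'   linearly from `base_prob` at the left edge to
#'   `base_prob + gradient_amplitude` at the right edge (global x across
#'   tile columns), emulating the small but consistent base-percentage
#'   difference between the two ends of a lane.
#' * `cycle_symbol`/`cycle_period`/`cycle_amplitude` — a periodic
#'   per-cycle excess of one symbol at every cycle divisible by
#'   `cycle_period` (1-based), emulating cyclic color-code bias locked to
#'   chemistry rounds such as the 5-cycle primer-reset pattern.
#' * `tile_quality_shift` — named vector of additive Phred shifts for
#'   designated tiles (a low-quality band near the sample inlet).
#' * `density_mask` — a `gx x gy` matrix of relative cell weights applied
#'   identically on every tile (a donut or stripe from the optics); reads
#'   land in cell `(i, j)` with probability proportional to the weight.
#' * `tile_density_mask` — a named list of such matrices applied to
#'   specific tiles only (a defect confined to one tile), overriding
#'   `density_mask` there.
#' * `tile_weights` — named per-tile expected read-count weights
#'   (default equal across used tiles).
#' * `no_call_rate` — per-symbol probability of an uncalled position
#'   (`N`/`.`).
#'
#' At most one of gradient/cycle bias symbols may differ from the other:
#' both effects must target the same symbol when both are active.
#'
#' @param gradient_symbol,gradient_amplitude Spatial gradient spec.
#' @param cycle_symbol,cycle_period,cycle_amplitude Cyclic bias spec.
#' @param tile_quality_shift Named numeric vector of per-tile Phred shifts.
#' @param density_mask Matrix of non-negative cell weights.
#' @param tile_density_mask Named list (by tile id) of per-tile weight
#'   matrices.
#' @param tile_weights Named numeric vector of per-tile weights.
#' @param no_call_rate Probability of a no-call per symbol.
#' @param base_prob Baseline probability of each symbol (uniform alphabet).
#' @param qual_mean,qual_sd,qual_cycle_slope Quality model: scores are
#'   `round(rnorm(qual_mean + qual_cycle_slope * (cycle - 1) + tile shift,
#'   qual_sd))`, clipped to `[2, 40]`.
#' @return A list of class `flowcell_effects`.
#' @export
flowcell_effects <- function(gradient_symbol = NULL, gradient_amplitude = 0,
                             cycle_symbol = NULL, cycle_period = 5L,
                             cycle_amplitude = 0,
                             tile_quality_shift = NULL,
                             density_mask = NULL,
                             tile_density_mask = NULL,
                             tile_weights = NULL,
                             no_call_rate = 0.002,
                             base_prob = 0.25,
                             qual_mean = 34, qual_sd = 3,
                             qual_cycle_slope = -0.1) {
  eff <- list(gradient_symbol = gradient_symbol,
              gradient_amplitude = gradient_amplitude,
              cycle_symbol = cycle_symbol, cycle_period = as.integer(cycle_period),
              cycle_amplitude = cycle_amplitude,
              tile_quality_shift = tile_quality_shift,
              density_mask = density_mask, tile_density_mask = tile_density_mask,
              tile_weights = tile_weights,
              no_call_rate = no_call_rate, base_prob = base_prob,
              qual_mean = qual_mean, qual_sd = qual_sd,
              qual_cycle_slope = qual_cycle_slope)
  pmax_ <- base_prob + max(0, gradient_amplitude) + max(0, cycle_amplitude)
  pmin_ <- base_prob + min(0, gradient_amplitude) + min(0, cycle_amplitude)
  if (pmax_ > 1 || pmin_ < 0) {
    stopf("infeasible effect spec: biased-symbol probability leaves [0, 1] (range %.3f-%.3f)",
          pmin_, pmax_)
  }
  if (!is.null(gradient_symbol) && !is.null(cycle_symbol) &&
      gradient_symbol != cycle_symbol) {
    stopf("gradient and cycle bias must target the same symbol when both are set")
  }
  if (!is.null(density_mask) && any(density_mask < 0)) {
    stopf("density_mask weights must be non-negative")
  }
  if (!is.null(tile_density_mask) &&
      (is.null(names(tile_density_mask)) ||
       any(vapply(tile_density_mask, function(m) any(m < 0), logical(1))))) {
    stopf("tile_density_mask must be a named list of non-negative weight matrices")
  }
  if (no_call_rate < 0 || no_call_rate >= 1) stopf("no_call_rate must be in [0, 1)")
  class(eff) <- "flowcell_effects"
  eff
}

#' Simulate a flowcell of reads with known injected biases
#'
#' Generates a full read set over a layout, with every bias under the
#' caller's control (see [flowcell_effects()]), so each QC metric can be
#' validated against ground truth. Read identifiers encode the true
#' (tile, x, y) in a supported dialect, so parsing them recovers the drawn
#' coordinates exactly; output is deterministic given the seed.
#'
#' @param layout A [flowcell_layout()]; reads land only on used tiles.
#' @param n_reads Number of reads.
#' @param read_length Cycles per read.
#' @param alphabet `"base"` (A/C/G/T, FASTQ output) or `"color"`
#'   (SOLiD color codes, csfasta+qual output).
#' @param effects A [flowcell_effects()] spec.
#' @param seed Integer seed governing all randomness.
#' @param dialect Read-id dialect (default `"casava18"` for basespace,
#'   `"solid"` for colorspace).
#' @param dir If non-NULL, write read files and a truth sidecar there.
#' @param name Sample name used for file names and read-id prefixes.
#' @return A list of class `flowcell_sim`: `reads` (tibble shaped like
#'   [read_fastq()] output), `truth` (seed, layout, effect parameters and
#'   exact per-tile read counts), and `files` (named paths when `dir` was
#'   given).
#' @export
simulate_flowcell <- function(layout, n_reads = 1e5, read_length = 35L,
                              alphabet = c("base", "color"),
                              effects = flowcell_effects(), seed = 1L,
                              dialect = NULL, dir = NULL, name = "sim") {
  stopifnot(inherits(layout, "flowcell_layout"))
  alphabet <- match.arg(alphabet)
  if (!inherits(effects, "flowcell_effects")) stopf("effects must come from flowcell_effects()")
  n <- as.integer(n_reads); L <- as.integer(read_length)
  syms <- switch(alphabet, base = c("A", "C", "G", "T"), color = c("0", "1", "2", "3"))
  no_call <- switch(alphabet, base = "N", color = ".")
  dialect <- dialect %||% switch(alphabet, base = "casava18", color = "solid")
  set.seed(seed)

  tl <- layout$tiles
  used <- which(!tl$unused)
  w <- rep(1, length(used))
  if (!is.null(effects$tile_weights)) {
    w <- effects$tile_weights[tl$tile_id[used]]
    if (anyNA(w)) stopf("tile_weights must cover every used tile")
  }
  ti <- sample(used, n, replace = TRUE, prob = w)

  draw_xy <- function(k, mask) {
    if (!is.null(mask)) {
      gmx <- nrow(mask); gmy <- ncol(mask)
      cell <- sample.int(gmx * gmy, k, replace = TRUE, prob = as.vector(mask))
      cgx <- (cell - 1L) %% gmx
      cgy <- (cell - 1L) %/% gmx
      list(x = as.integer(floor((cgx + runif(k)) / gmx * layout$tile_x)),
           y = as.integer(floor((cgy + runif(k)) / gmy * layout$tile_y)))
    } else {
      list(x = as.integer(floor(runif(k) * layout$tile_x)),
           y = as.integer(floor(runif(k) * layout$tile_y)))
    }
  }
  assign_xy <- function(idx, x, y) {
    tdm <- effects$tile_density_mask
    special <- if (is.null(tdm)) character() else
      intersect(names(tdm), unique(tl$tile_id[ti[idx]]))
    plain <- idx[!(tl$tile_id[ti[idx]] %in% special)]
    if (length(plain)) {
      r <- draw_xy(length(plain), effects$density_mask)
      x[plain] <- r$x; y[plain] <- r$y
    }
    for (tid in special) {
      sel <- idx[tl$tile_id[ti[idx]] == tid]
      r <- draw_xy(length(sel), tdm[[tid]])
      x[sel] <- r$x; y[sel] <- r$y
    }
    list(x = x, y = y)
  }
  x <- integer(n); y <- integer(n)
  xy <- assign_xy(seq_len(n), x, y)
  x <- xy$x; y <- xy$y
  # read ids must be unique: redraw coordinate collisions within a tile
  repeat {
    dup <- which(duplicated(paste(ti, x, y)))
    if (!length(dup)) break
    xy <- assign_xy(dup, x, y)
    x <- xy$x; y <- xy$y
  }

  # biased-symbol probability per read (gradient over global x) and per cycle
  biased <- effects$gradient_symbol %||% effects$cycle_symbol
  p_read <- rep(effects$base_prob, n)
  if (!is.null(effects$gradient_symbol) && effects$gradient_amplitude != 0) {
    gpos <- (tl$col[ti] + (x + 0.5) / layout$tile_x) / layout$cols
    p_read <- p_read + effects$gradient_amplitude * gpos
  }
  d_cycle <- numeric(L)
  if (!is.null(effects$cycle_symbol) && effects$cycle_amplitude != 0) {
    d_cycle[seq_len(L) %% effects$cycle_period == 0L] <- effects$cycle_amplitude
  }
  p1 <- outer(p_read, d_cycle, `+`)
  u <- matrix(runif(n * L), n, L)
  code <- matrix(2L, n, L)
  hit1 <- u < p1
  v <- (u - p1) / (1 - p1)
  code <- 2L + pmin(2L, floor(v * 3))
  code[hit1] <- 1L
  # map code 1 -> biased symbol position, 2..4 -> the others in order
  perm <- seq_len(4L)
  if (!is.null(biased)) {
    b <- match(biased, syms)
    if (is.na(b)) stopf("biased symbol '%s' not in the %s alphabet", biased, alphabet)
    perm <- c(b, setdiff(seq_len(4L), b))
  }
  sym_idx <- matrix(perm[code], n, L)
  chars <- matrix(syms[sym_idx], n, L)
  if (effects$no_call_rate > 0) {
    nc <- matrix(runif(n * L) < effects$no_call_rate, n, L)
    chars[nc] <- no_call
  }
  symbols <- collapse_rows(chars)

  shift <- rep(0, n)
  if (!is.null(effects$tile_quality_shift)) {
    s <- effects$tile_quality_shift[tl$tile_id[ti]]
    s[is.na(s)] <- 0
    shift <- as.numeric(s)
  }
  qmean <- outer(shift + effects$qual_mean, effects$qual_cycle_slope * (seq_len(L) - 1L), `+`)
  q <- matrix(as.integer(pmin(40, pmax(2, round(rnorm(n * L, mean = qmean,
                                                      sd = effects$qual_sd))))), n, L)
  quals <- collapse_rows(matrix(intToUtf8(q + 33L, multiple = TRUE), n, L))

  mate <- if (alphabet == "color") "F3" else "1"
  ids <- format_read_id(dialect, tl$tile_id[ti], x, y, mate,
                        prefix = toupper(name))
  reads <- tibble(read_id = ids, tile_id = tl$tile_id[ti], x = x, y = y,
                  mate = if (alphabet == "color") mate else "1",
                  symbols = symbols, quals = quals)
  attr(reads, "alphabet") <- alphabet
  attr(reads, "qual_offset") <- 33L
  attr(reads, "n_records") <- n
  attr(reads, "n_coordless") <- 0L
  attr(reads, "n_unknown_tile") <- 0L
  attr(reads, "n_out_of_bounds") <- 0L

  truth <- list(seed = seed, n_reads = n, read_length = L, alphabet = alphabet,
                dialect = dialect, layout = layout, effects = effects,
                tile_counts = setNames(tabulate(ti, nrow(tl)), tl$tile_id))
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (alphabet == "base") {
      fq <- file.path(dir, paste0(name, ".fastq"))
      writeLines(as.vector(rbind(paste0("@", ids), symbols, "+", quals)), fq)
      files <- c(reads = fq)
    } else {
      cf <- file.path(dir, paste0(name, ".csfasta"))
      qf <- file.path(dir, paste0(name, ".qual"))
      writeLines(as.vector(rbind(paste0(">", ids), paste0("T", symbols))), cf)
      qlines <- vapply(seq_len(n), function(i) paste(q[i, ], collapse = " "),
                       character(1))
      writeLines(as.vector(rbind(paste0(">", ids), qlines)), qf)
      files <- c(csfasta = cf, qual = qf)
    }
    tf <- file.path(dir, paste0(name, ".truth"))
    write_truth(truth, tf)
    files <- c(files, truth = tf)
  }
  structure(list(reads = reads, truth = truth, files = files),
            class = "flowcell_sim")
}

# key-value sidecar describing what was injected
write_truth <- function(truth, path) {
  eff <- truth$effects
  kv <- c(
    seed = truth$seed, n_reads = truth$n_reads, read_length = truth$read_length,
    alphabet = truth$alphabet, dialect = truth$dialect,
    gradient_symbol = eff$gradient_symbol %||% "none",
    gradient_amplitude = eff$gradient_amplitude,
    cycle_symbol = eff$cycle_symbol %||% "none",
    cycle_period = eff$cycle_period, cycle_amplitude = eff$cycle_amplitude,
    no_call_rate = eff$no_call_rate,
    tile_counts = paste(sprintf("%s:%d", names(truth$tile_counts),
                                truth$tile_counts), collapse = " ")
  )
  writeLines(sprintf("%s: %s", names(kv), as.character(kv)), path)
  invisible(path)
}

#' Simulate alignments for a simulated flowcell
#'
#' Produces a SAM file (and its in-memory tibble) for the reads of a
#' [simulate_flowcell()] run, with controlled per-cycle substitution rates,
#' per-tile mappability and an optional multi-hit fraction. NM and MD tags
#' are constructed to be exactly consistent with the injected mismatch
#' mask (MD written in reference order, i.e. reversed for minus-strand
#' hits), so tag-derived statistics can be checked against truth.
#'
#' @param sim A `flowcell_sim` (basespace only).
#' @param reference_length Length of the single simulated reference
#'   (`ref1`).
#' @param per_cycle_rate Substitution probability per cycle: a scalar, a
#'   vector of length `read_length`, or a function `(cycle, read_length)`.
#' @param tile_mappability Named per-tile probability that a read maps
#'   (default 1 everywhere); unmapped reads are emitted as SAM unmapped
#'   records.
#' @param multi_hit_rate Fraction of mapped reads that receive a second
#'   (multi-hit) alignment record.
#' @param seed Integer seed.
#' @param path SAM output file (default a tempfile).
#' @return A list of class `alignment_sim`: `sam` (path), `truth`
#'   (per-tile mapped counts, the per-cycle rate vector used, seed).
#' @export
simulate_alignments <- function(sim, reference_length = 1e6,
                                per_cycle_rate = 0,
                                tile_mappability = NULL,
                                multi_hit_rate = 0,
                                seed = 1L, path = tempfile(fileext = ".sam")) {
  stopifnot(inherits(sim, "flowcell_sim"))
  if (sim$truth$alphabet != "base") {
    stopf("alignment simulation supports basespace reads only")
  }
  reads <- sim$reads
  n <- nrow(reads); L <- sim$truth$read_length
  set.seed(seed)
  rate <- if (is.function(per_cycle_rate)) {
    vapply(seq_len(L), per_cycle_rate, numeric(1), L)
  } else if (length(per_cycle_rate) == 1L) {
    rep(per_cycle_rate, L)
  } else {
    stopifnot(length(per_cycle_rate) == L)
    as.numeric(per_cycle_rate)
  }
  if (any(rate < 0 | rate > 1)) stopf("per-cycle substitution rates must be in [0, 1]")
  mp <- rep(1, n)
  if (!is.null(tile_mappability)) {
    m <- tile_mappability[reads$tile_id]
    mp <- ifelse(is.na(m), 1, as.numeric(m))
  }
  mapped <- runif(n) < mp
  pos0 <- as.integer(floor(runif(n) * (reference_length - L)))
  strand <- ifelse(runif(n) < 0.5, "+", "-")
  mask <- matrix(runif(n * L) < rep(rate, each = n), n, L)  # read-cycle order
  mask[!mapped, ] <- FALSE
  nm <- rowSums(mask)

  ids <- normalize_read_ids(reads$read_id)
  seqs <- reads$symbols
  neg <- which(strand == "-" & mapped)
  if (length(neg)) {
    seqs[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(chartr(".", "N", seqs[neg]))))
  }
  md <- md_strings(mask, strand, seqs, L)
  extra <- if (multi_hit_rate > 0) which(mapped & runif(n) < multi_hit_rate) else integer()
  mapq <- ifelse(mapped, 60L, 0L)
  mapq[extra] <- 0L
  flag <- ifelse(!mapped, 4L, ifelse(strand == "-", 16L, 0L))
  recs <- ifelse(mapped,
    sprintf("%s\t%d\tref1\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d\tMD:Z:%s",
            ids, flag, pos0 + 1L, mapq, L, seqs, reads$quals, nm, md),
    sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s", ids, reads$symbols, reads$quals))
  if (length(extra)) {
    alt <- as.integer(floor(runif(length(extra)) * (reference_length - L)))
    recs <- c(recs,
              sprintf("%s\t%d\tref1\t%d\t0\t%dM\t*\t0\t0\t*\t*\tNM:i:%d\tMD:Z:%s",
                      ids[extra], flag[extra] + 256L, alt + 1L, L,
                      nm[extra], md[extra]))
  }
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:ref1\tLN:%d", as.integer(reference_length)))
  writeLines(c(header, recs), path)
  truth <- list(seed = seed, rate = rate, n_mapped = sum(mapped),
                n_multi = length(extra),
                mask_colsums = colSums(mask[mapped, , drop = FALSE]),
                multi_ids = ids[extra])
  truth$tile_mapped <- setNames(
    as.integer(tapply(mapped, factor(reads$tile_id,
                                     levels = sim$truth$layout$tiles$tile_id),
                      sum, default = 0L)),
    sim$truth$layout$tiles$tile_id)
  structure(list(sam = path, truth = truth), class = "alignment_sim")
}

# MD tag strings (reference order) for a mismatch mask in read-cycle order
md_strings <- function(mask, strand, seqs, L) {
  n <- nrow(mask)
  out <- rep(sprintf("%d", L), n)
  idx <- which(rowSums(mask) > 0L)
  if (!length(idx)) return(out)
  # reference base must differ from the read base at the mismatch site
  sub_map <- c(A = "C", C = "G", G = "T", T = "A", N = "A")
  for (i in idx) {
    cyc <- which(mask[i, ])                       # read-cycle order, 1-based
    refpos <- if (strand[i] == "-") sort(L + 1L - cyc) else cyc
    seq_chars <- substring(seqs[i], refpos, refpos)  # seqs already ref-oriented
    letters_ <- unname(sub_map[seq_chars])
    letters_[is.na(letters_)] <- "A"
    gaps <- diff(c(0L, refpos)) - 1L
    out[i] <- paste0(paste0(gaps, letters_, collapse = ""), L - refpos[length(refpos)])
  }
  out
}

#' Simulate a paired-end alignment set with exact category counts
#'
#' Constructs a SAM file containing read pairs in specified numbers for
#' each library-QC category, so [summarize_pairs()] can be checked by
#' exact bookkeeping: running it on the output reproduces
#' `category_counts` exactly. Good pairs draw their absolute separation
#' from a normal insert distribution truncated to the configured range,
#' with convergent orientation and the sign of the distance tied to the
#' first end's strand.
#'
#' @param category_counts Named integer vector over the categories
#'   `good_pair`, `unpaired_forward`, `unpaired_reverse`,
#'   `different_chromosome`, `wrong_orientation`, `below_range`,
#'   `above_range` (missing names count 0).
#' @param config A [pair_config()].
#' @param insert_mean,insert_sd Normal insert-size distribution of good
#'   pairs (truncated to `[min_distance, max_distance]`).
#' @param read_length Read length recorded in the SAM records.
#' @param reference_lengths Named vector of simulated chromosomes (needs
#'   at least 2 for `different_chromosome`).
#' @param seed Integer seed.
#' @param path SAM output file.
#' @return A list of class `pair_sim`: `sam`, `truth` (the requested
#'   counts, insert parameters, seed).
#' @export
simulate_pairs <- function(category_counts, config = pair_config(),
                           insert_mean = 2000, insert_sd = 300,
                           read_length = 36L,
                           reference_lengths = c(chr1 = 5e6, chr2 = 5e6),
                           seed = 1L, path = tempfile(fileext = ".sam")) {
  counts <- setNames(integer(length(pair_category_levels)), pair_category_levels)
  bad <- setdiff(names(category_counts), pair_category_levels)
  if (length(bad)) stopf("unknown pair category '%s'", bad[1])
  counts[names(category_counts)] <- as.integer(category_counts)
  if (any(counts < 0)) stopf("category counts must be >= 0")
  set.seed(seed)
  L <- as.integer(read_length)
  refs <- names(reference_lengths)
  if (counts["different_chromosome"] > 0L && length(refs) < 2L) {
    stopf("different_chromosome pairs need at least two references")
  }
  lo <- config$min_distance; hi <- config$max_distance
  span <- function(k, ref) {
    lim <- reference_lengths[[ref]] - L - 3 * hi
    if (lim <= 0) stopf("reference '%s' too short for the configured range", ref)
    as.integer(floor(runif(k) * lim) + hi)
  }

  rows <- list()
  pid <- 0L
  emit <- function(k, f) {
    if (k == 0L) return(invisible())
    ids <- sprintf("p%07d", pid + seq_len(k))
    pid <<- pid + k
    rows[[length(rows) + 1L]] <<- f(k, ids)
    invisible()
  }
  rtrunc_insert <- function(k) {
    out <- numeric(0)
    while (length(out) < k) {
      cand <- round(rnorm(2L * k, insert_mean, insert_sd))
      out <- c(out, cand[cand >= lo & cand <= hi])
    }
    as.integer(out[seq_len(k)])
  }
  mk <- function(ids, ref1, s1, p1, ref2, s2, p2, un1 = FALSE, un2 = FALSE) {
    tibble(id = ids, ref1 = ref1, strand1 = s1, pos1 = p1, unmapped1 = un1,
           ref2 = ref2, strand2 = s2, pos2 = p2, unmapped2 = un2)
  }
  conv_pair <- function(k, ids, d_abs) {
    s1 <- ifelse(runif(k) < 0.5, "+", "-")
    p2 <- span(k, refs[1])
    # distance start1 - start2: negative when end1 is the forward read
    p1 <- as.integer(ifelse(s1 == "+", p2 - d_abs, p2 + d_abs))
    mk(ids, refs[1], s1, p1, refs[1], ifelse(s1 == "+", "-", "+"), p2)
  }
  emit(counts["good_pair"], function(k, ids) conv_pair(k, ids, rtrunc_insert(k)))
  emit(counts["below_range"], function(k, ids)
    conv_pair(k, ids, as.integer(floor(runif(k) * lo))))
  emit(counts["above_range"], function(k, ids)
    conv_pair(k, ids, hi + 1L + as.integer(floor(runif(k) * hi))))
  emit(counts["wrong_orientation"], function(k, ids) {
    s <- ifelse(runif(k) < 0.5, "+", "-")
    p2 <- span(k, refs[1])
    mk(ids, refs[1], s, p2 - rtrunc_insert(k), refs[1], s, p2)
  })
  emit(counts["different_chromosome"], function(k, ids) {
    mk(ids, refs[1], ifelse(runif(k) < 0.5, "+", "-"), span(k, refs[1]),
       refs[2], ifelse(runif(k) < 0.5, "+", "-"), span(k, refs[2]))
  })
  emit(counts["unpaired_forward"], function(k, ids) {
    mk(ids, refs[1], ifelse(runif(k) < 0.5, "+", "-"), span(k, refs[1]),
       NA_character_, NA_character_, NA_integer_, un2 = TRUE)
  })
  emit(counts["unpaired_reverse"], function(k, ids) {
    mk(ids, NA_character_, NA_character_, NA_integer_,
       refs[1], ifelse(runif(k) < 0.5, "+", "-"), span(k, refs[1]), un1 = TRUE)
  })
  tb <- dplyr::bind_rows(rows)
  sam_end <- function(id, ref, strand, pos, unmapped, first) {
    base <- 1L + if (first) 64L else 128L
    ifelse(unmapped,
      sprintf("%s\t%d\t*\t0\t0\t*\t*\t0\t0\t*\t*", id, base + 4L),
      sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*\tNM:i:0\tMD:Z:%d",
              id, base + ifelse(strand == "-", 16L, 0L), ref, pos + 1L, L, L))
  }
  recs <- c()
  if (nrow(tb)) {
    recs <- as.vector(rbind(
      sam_end(tb$id, tb$ref1, tb$strand1, tb$pos1, tb$unmapped1, TRUE),
      sam_end(tb$id, tb$ref2, tb$strand2, tb$pos2, tb$unmapped2, FALSE)))
  }
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", refs, as.integer(reference_lengths)))
  writeLines(c(header, recs), path)
  truth <- list(seed = seed, counts = counts, insert_mean = insert_mean,
                insert_sd = insert_sd, config = config)
  structure(list(sam = path, truth = truth), class = "pair_sim")
}
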
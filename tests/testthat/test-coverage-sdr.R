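# Windowed depth, normalisation, SDR calling (with a brute-force merged-run
# oracle) and repeat-density summarisation.

test_that("windowed depth averages per-base depth with absent bases as zero", {
  # uniform depth 10 over 10 kb -> 10 windows of 10
  src <- data.frame(chrom = "c1", pos = 1:10000, depth = 10)
  tr <- compute_windowed_depth(src, window = 1000)
  expect_equal(nrow(tr), 10)
  expect_true(all(tr$depth == 10))
  # depth 10 over first half of one window, nothing on second half -> 5
  half <- data.frame(chrom = "c1", pos = 1:500, depth = 10)
  tr2 <- compute_windowed_depth(half, window = 1000,
                                chrom_lengths = c(c1 = 1000))
  expect_equal(tr2$depth, 5)
  expect_error(compute_windowed_depth(src, window = 50), ">= 100")
  expect_error(
    compute_windowed_depth(src, window = 1000, chrom_lengths = c(zz = 100)),
    "unknown chromosome")
  # TSV round trip
  tsv <- tempfile(fileext = ".tsv")
  write.table(src, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(compute_windowed_depth(tsv, window = 1000)$depth, tr$depth)
})

test_that("windowed depth can be extracted from a BAM with a mapq filter", {
  # two 100 bp reads on c1: one mapq 60 at pos 1, one mapq 5 at pos 201
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:c1\tLN:1000",
    paste("r1", 0, "c1", 1, 60, "100M", "*", 0, 0,
          paste(rep("A", 100), collapse = ""),
          paste(rep("I", 100), collapse = ""), sep = "\t"),
    paste("r2", 0, "c1", 201, 5, "100M", "*", 0, 0,
          paste(rep("A", 100), collapse = ""),
          paste(rep("I", 100), collapse = ""), sep = "\t")), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  tr <- compute_windowed_depth(bam, window = 100,
                               chrom_lengths = c(c1 = 1000), min_mapq = 20)
  expect_equal(tr$depth[1], 1)   # high-mapq read counted
  expect_equal(tr$depth[3], 0)   # low-mapq read filtered
  tr_all <- compute_windowed_depth(bam, window = 100,
                                   chrom_lengths = c(c1 = 1000), min_mapq = 0)
  expect_equal(tr_all$depth[3], 1)
})

test_that("normalisation sets the autosomal median to one and is scale equivariant", {
  tr <- depth_track(rep(c("A1", "Y"), each = 5), rep(0:4 * 100, 2),
                    rep(1:5 * 100, 2), c(rep(40, 5), rep(20, 5)))
  nt <- normalize_track(tr, "A1")
  expect_equal(nt$depth, c(rep(1, 5), rep(0.5, 5)))
  # scaling all depths leaves the normalized track unchanged
  tr3 <- tr; tr3$depth <- tr3$depth * 3.7
  expect_equal(normalize_track(tr3, "A1")$depth, nt$depth)
  expect_error(normalize_track(tr, character(0)), "non-empty")
  zero <- tr; zero$depth <- 0
  expect_error(normalize_track(zero, "A1"), "zero")
})

test_that("SDR calling matches its contract on constructed tracks", {
  mk <- function(f, m) {
    n <- length(f)
    list(f = depth_track("Y", 0:(n - 1) * 100, 1:n * 100, f, "f"),
         m = depth_track("Y", 0:(n - 1) * 100, 1:n * 100, m, "m"))
  }
  # identical tracks: no call
  t1 <- mk(rep(1, 20), rep(1, 20))
  expect_equal(nrow(call_sdr(t1$f, t1$m)), 0)
  # run shorter than min_windows: no call
  t2 <- mk(c(rep(1, 8), rep(0.01, 4), rep(1, 8)), rep(1, 20))
  expect_equal(nrow(call_sdr(t2$f, t2$m, min_windows = 5)), 0)
  expect_equal(nrow(call_sdr(t2$f, t2$m, min_windows = 4)), 1)
  # gap tolerance merges across interior non-candidates
  f <- c(rep(0.01, 6), 1, 1, rep(0.01, 6), rep(1, 6))
  t3 <- mk(f, rep(1, length(f)))
  calls <- call_sdr(t3$f, t3$m, max_gap_windows = 2)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$n_windows, 14)
  calls0 <- call_sdr(t3$f, t3$m, max_gap_windows = 1)
  expect_equal(nrow(calls0), 2)
  # mismatched grids rejected
  t4 <- mk(rep(1, 19), rep(1, 19))
  expect_error(call_sdr(t1$f, t4$m), "grids")
})

test_that("SDR calling equals the union-find merged-run oracle on random tracks", {
  set.seed(99)
  for (rep_i in 1:40) {
    n <- sample(10:50, 1)
    f <- ifelse(runif(n) < 0.4, 0.01, 1)
    tr_f <- depth_track("c", 0:(n - 1) * 100, 1:n * 100, f, "f")
    tr_m <- depth_track("c", 0:(n - 1) * 100, 1:n * 100, rep(1, n), "m")
    gap <- sample(0:3, 1); minw <- sample(1:6, 1)
    calls <- call_sdr(tr_f, tr_m, ratio_threshold = 0.3, min_windows = minw,
                      max_gap_windows = gap)
    runs <- oracle_merged_runs(f < 0.3, gap)
    runs <- runs[runs[, 2] - runs[, 1] + 1 >= minw, , drop = FALSE]
    expect_equal(nrow(calls), nrow(runs))
    if (nrow(calls)) {
      expect_equal(calls$start, (runs[, 1] - 1) * 100)
      expect_equal(calls$end, runs[, 2] * 100)
    }
  }
})

test_that("simulated truth is recovered within one window across seeds", {
  hits <- 0L
  for (s in 1:20) {
    cfg <- sim_config(seed = s, n_gametologs = 2, n_x_specific = 0,
                      n_y_specific = 0, n_par_pairs = 1)
    d <- simulate_pool_depth(cfg$sdr_span, cfg, window = 1000)
    f <- normalize_track(d$female, "A1")
    m <- normalize_track(d$male, "A1")
    calls <- call_sdr(f, m)
    ok <- nrow(calls) == 1 && calls$chrom == "Y" &&
      abs(calls$start - cfg$sdr_span$start) <= 1000 &&
      abs(calls$end - cfg$sdr_span$end) <= 1000
    hits <- hits + ok
  }
  expect_gte(hits, 19)
})

test_that("repeat density reports per-class union coverage fractions", {
  win <- data.frame(chrom = "Y", start = c(0, 1000), end = c(1000, 2000))
  reps <- data.frame(chrom = "Y",
                     start = c(0, 100, 500, 1500),
                     end = c(1000, 600, 900, 1800),
                     class = c("LTR/Gypsy", "LTR/Copia", "LTR/Copia", "LINE"))
  rd <- summarize_repeat_density(reps, win)
  expect_equal(rd[["LTR/Gypsy"]], c(1, 0))
  # overlapping same-class intervals count once: union [100,900) = 0.8
  expect_equal(rd[["LTR/Copia"]], c(0.8, 0))
  expect_equal(rd[["LINE"]], c(0, 0.3))
  expect_equal(rd$total, c(1, 0.3))
  expect_true(all(rd$total + 1e-12 >= rd[["LTR/Gypsy"]]))
  # half Gypsy, half Copia -> total 1.0
  win2 <- data.frame(chrom = "Y", start = 0, end = 1000)
  reps2 <- data.frame(chrom = "Y", start = c(0, 500), end = c(500, 1000),
                      class = c("LTR/Gypsy", "LTR/Copia"))
  rd2 <- summarize_repeat_density(reps2, win2)
  expect_equal(rd2[["LTR/Gypsy"]], 0.5)
  expect_equal(rd2$total, 1)
  # malformed BED reports the line number
  bad <- tempfile(fileext = ".bed")
  writeLines(c("Y\t0\t100\tLINE", "Y\tx\t200\tLINE"), bad)
  expect_error(summarize_repeat_density(bad, win), "line 2")
})
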
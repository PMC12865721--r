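# Simulator contracts: configuration invariants, determinism, truth
# conservation, and calibration of depth / divergence / diversity targets.

small_cfg <- function(seed = 11, ...) {
  sim_config(seed = seed, n_gametologs = 10, n_x_specific = 3,
             n_y_specific = 2, n_par_pairs = 3, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(sim_config(sdr_span = region("Y", 0, 50000),
                          par_span = region("Y", 40000, 60000)),
               "overlaps")
  expect_error(sim_config(true_ks = 0.8), "0.75")
  expect_error(sim_config(pool_depth = 0), "positive")
  expect_error(sim_config(n_haplotypes = 3), ">= 4|even")
  expect_error(sim_config(theta_by_region = c(X = 0.2)), "0.1")
  expect_error(sim_config(sdr_span = region("Y", 0, 70000)),
               "exceeds")
  expect_error(region("Y", 10, 10), "invalid")
})

test_that("genome simulation respects configured lengths and is deterministic", {
  cfg <- small_cfg()
  g1 <- simulate_sex_genome(cfg)
  expect_equal(unname(nchar(g1$genome)), unname(cfg$chrom_lengths),
               ignore_attr = TRUE)
  d1 <- file.path(tempdir(), "sim1"); d2 <- file.path(tempdir(), "sim2")
  simulate_sex_genome(cfg, out_dir = d1)
  simulate_sex_genome(cfg, out_dir = d2)
  for (f in c("genome.fa", "cds.fa", "genes.gff3"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # different seed changes the sequence
  g2 <- simulate_sex_genome(small_cfg(seed = 12))
  expect_false(identical(g1$genome, g2$genome))
})

test_that("every simulated gene is covered exactly once by the truth partition", {
  g <- simulate_sex_genome(small_cfg())
  sdr_ids <- g$genes$id[g$genes$region == "SDR"]
  claimed <- c(g$truth$gametolog_truth$y_id, g$truth$y_specific)
  expect_setequal(sdr_ids, claimed)
  all_claimed <- c(g$truth$gametolog_truth$x_id, g$truth$gametolog_truth$y_id,
                   g$truth$x_specific, g$truth$y_specific,
                   g$genes$id[g$genes$region == "PAR"])
  expect_setequal(g$genes$id, all_claimed)
  expect_equal(anyDuplicated(all_claimed), 0)
})

test_that("pool depths follow the configured Poisson means", {
  cfg <- small_cfg(pool_depth = 40, leak = 0.02)
  d <- simulate_pool_depth(cfg$sdr_span, cfg, window = 1000)
  auto_f <- d$female$depth[d$female$chrom == "A1"]
  sdr_f <- d$female$depth[d$female$chrom == "Y" & d$female$end <= 40000]
  sdr_m <- d$male$depth[d$male$chrom == "Y" & d$male$end <= 40000]
  # Poisson standard error bound: 3 * sqrt(mean / n_windows)
  expect_lt(abs(mean(auto_f) - 40), 3 * sqrt(40 / length(auto_f)))
  expect_lt(abs(mean(sdr_m) - 20), 3 * sqrt(20 / length(sdr_m)))
  expect_lt(abs(mean(sdr_f) - 0.8), 3 * sqrt(0.8 / length(sdr_f)))
  # female/male SDR ratio approx 2 * leak over >= 100 windows
  cfg2 <- sim_config(seed = 3, chrom_lengths = c(A1 = 50000, X = 30000, Y = 150000),
                     sdr_span = region("Y", 0, 120000),
                     par_span = region("Y", 120000, 150000),
                     n_gametologs = 5, pool_depth = 60)
  d2 <- simulate_pool_depth(cfg2$sdr_span, cfg2, window = 1000)
  i <- d2$female$chrom == "Y" & d2$female$end <= 120000
  expect_gte(sum(i), 100)
  ratio <- mean(d2$female$depth[i]) / mean(d2$male$depth[i])
  expect_equal(ratio, 2 * cfg2$leak, tolerance = 0.25)
  # windows tile the chromosomes exactly
  lens <- tapply(d$female$end - d$female$start, d$female$chrom, sum)
  expect_equal(as.numeric(lens[names(cfg$chrom_lengths)]),
               unname(cfg$chrom_lengths))
  expect_error(simulate_pool_depth(cfg$sdr_span, cfg, window = 2e6),
               "window")
})

test_that("gametolog evolution hits its divergence targets", {
  cfg <- small_cfg(true_ks = 0.3, ks_sd = 0.05)
  ev <- evolve_gametologs(cfg, n_pairs = 12)
  expect_equal(nrow(ev$truth), 12)
  # realised divergence tracks the drawn target (one-mutation overshoot)
  expect_true(all(ev$truth$realised_ks >= ev$truth$true_ks))
  expect_true(all(ev$truth$realised_ks - ev$truth$true_ks < 0.05))
  # no internal stop codons in any emitted CDS
  for (s in ev$cds) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(cods %in% STOP_CODONS))
  }
  # zero target emits an identical pair
  p0 <- with(list(), {
    set.seed(2)
    SDRtools:::evolve_pair(0, 0, 50L)
  })
  expect_identical(p0$x, p0$y)
  expect_error(SDRtools:::evolve_pair(0.8, 0, 50L), "saturation")
})

test_that("population VCF respects the neutral sprinkling contract", {
  cfg <- small_cfg()
  v <- simulate_population_vcf(cfg)
  # positions strictly increasing per chromosome
  for (ch in unique(v$variants$chrom))
    expect_false(is.unsorted(v$variants$pos[v$variants$chrom == ch],
                             strictly = TRUE))
  # derived counts within 1..n-1 and genotypes match them
  expect_true(all(v$variants$j >= 1 & v$variants$j <= cfg$n_haplotypes - 1))
  expect_equal(as.integer(rowSums(v$gt)), v$variants$j)
  # zero-theta region emits nothing
  cfg0 <- small_cfg(theta_by_region = c(X = 0.003, SDR = 0))
  v0 <- simulate_population_vcf(cfg0)
  expect_equal(sum(v0$variants$region == "SDR"), 0)
  expect_error(
    simulate_population_vcf(small_cfg(theta_by_region = c(nope = 0.001))),
    "matches no chromosome")
  # deterministic per seed, including the written file
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  simulate_population_vcf(cfg, out_vcf = f1)
  simulate_population_vcf(cfg, out_vcf = f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("realized diversity recovers the configured theta", {
  # 1 Mb X region at theta 0.003, 20 haplotypes, 5 seeds
  pis <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = s, chrom_lengths = c(A1 = 10000, X = 1e6, Y = 20000),
                      sdr_span = region("Y", 0, 10000),
                      par_span = region("Y", 10000, 20000),
                      n_gametologs = 2, n_par_pairs = 1,
                      theta_by_region = c(X = 0.003))
    v <- simulate_population_vcf(cfg)
    k <- v$variants$class == "SNP" & v$variants$chrom == "X"
    nucleotide_diversity(v$variants$j[k], cfg$n_haplotypes, 1e6)
  }, numeric(1))
  expect_lt(abs(mean(pis) - 0.003) / 0.003, 0.15)
})

test_that("anchor permutations reproduce the requested structure", {
  a <- make_anchor_permutation(150, list(c(1, 65), c(66, 150)))
  expect_equal(a$y_rank, c(65:1, 150:66))
  expect_equal(make_anchor_permutation(10, list())$y_rank, 1:10)
  expect_equal(make_anchor_permutation(10, list(c(1, 10)))$y_rank, 10:1)
  expect_error(make_anchor_permutation(10, list(c(1, 5), c(4, 8))),
               "overlap")
  expect_error(make_anchor_permutation(10, list(c(0, 5))), "within")
  tsv <- tempfile(fileext = ".tsv")
  make_anchor_permutation(5, list(c(2, 4)), out_tsv = tsv)
  back <- read.delim(tsv)
  expect_equal(back$y_rank, c(1, 4, 3, 2, 5))
})
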
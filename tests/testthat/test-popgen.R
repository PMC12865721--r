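# Variant classification, nucleotide diversity (brute-force pairwise
# oracle), Tajima's D, Hudson's FST, and the X-vs-Y contrast report.

test_that("variant classes follow the ref/alt length rules with multiallelic splitting", {
  vt <- data.frame(chrom = "X", pos = c(10, 20, 30, 40, 50),
                   ref = c("A", "A", "ATG", "A", "CT"),
                   alt = c("T", "ATG", "A", "T,ATT", "GA"),
                   stringsAsFactors = FALSE)
  cl <- classify_variants(vt, chrom_lengths = c(X = 1000))
  expect_equal(cl$variants$class,
               c("SNP", "insertion", "deletion", "SNP", "insertion", "other"))
  expect_equal(cl$total, 6)  # conservation after splitting
  expect_equal(sum(cl$counts), cl$total)
  expect_equal(cl$density_per_kb, 6)
  # density needs lengths: NA without them, error when a length is missing
  expect_true(is.na(classify_variants(vt)$density_per_kb))
  expect_error(classify_variants(vt, chrom_lengths = c(Z = 10)),
               "missing contig length")
  bad <- vt; bad$pos <- rev(bad$pos)
  expect_error(classify_variants(bad, chrom_lengths = c(X = 1000)),
               "increasing")
})

test_that("classification round-trips through a written VCF with contig headers", {
  cfg <- sim_config(seed = 51, n_gametologs = 2, n_par_pairs = 1)
  f <- tempfile(fileext = ".vcf")
  v <- simulate_population_vcf(cfg, out_vcf = f)
  cl <- classify_variants(f)
  expect_equal(cl$total, nrow(v$variants))
  expect_equal(unname(cl$counts["SNP"]), sum(v$variants$class == "SNP"))
  expect_equal(cl$n_indels, sum(v$variants$class != "SNP"))
  # density uses ##contig lengths of the chromosomes carrying variants
  lens <- cfg$chrom_lengths[unique(v$variants$chrom)]
  expect_equal(cl$density_per_kb, cl$total / (sum(lens) / 1000))
  # allele counts from the file agree with the simulator matrix
  ac <- vcf_allele_counts(f)
  sim_ac <- vcf_allele_counts(c(v, list()))
  expect_equal(ac$j, sim_ac$j)
  expect_true(all(ac$n == cfg$n_haplotypes))
})

test_that("pi equals the brute-force pairwise average on small windows", {
  # 2 haplotypes differing at 1 of 100 sites
  expect_equal(nucleotide_diversity(1, 2, 100), 0.01)
  # 4 haplotypes, one site with j = 2: site term 2*2*2/(4*3) = 2/3
  expect_equal(nucleotide_diversity(2, 4, 50), (2 / 3) / 50)
  expect_equal(nucleotide_diversity(integer(0), 8, 100), 0)
  # random 0/1 haplotype matrices, n <= 8: exact oracle equivalence
  set.seed(77)
  for (rep_i in 1:30) {
    n <- sample(c(2, 4, 6, 8), 1)
    S <- sample(1:20, 1)
    gt <- matrix(rbinom(S * n, 1, runif(1, 0.1, 0.9)), S, n)
    L <- 500
    j <- rowSums(gt)
    expect_equal(nucleotide_diversity(j, n, L), oracle_pi_bruteforce(gt, L),
                 tolerance = 1e-12)
  }
})

test_that("tajima's d matches an independent evaluation and sign properties", {
  expect_equal(tajimas_d(16, 10, 3.888), -1.4468996, tolerance = 1e-6)
  expect_true(is.na(tajimas_d(0, 10, 0)))
  expect_error(tajimas_d(5, 3, 1), "n >= 4")
  n <- 20
  # excess of singletons -> negative D
  S <- 40
  pi_singletons <- sum(rep(2 * 1 * (n - 1) / (n * (n - 1)), S))
  expect_lt(tajimas_d(S, n, pi_singletons), 0)
  # excess of intermediate-frequency sites -> positive D
  pi_mid <- sum(rep(2 * (n / 2) * (n / 2) / (n * (n - 1)), S))
  expect_gt(tajimas_d(S, n, pi_mid), 0)
})

test_that("windowed diversity near-neutrality: mean D around zero under the neutral SFS", {
  cfg <- sim_config(seed = 61, chrom_lengths = c(A1 = 10000, X = 600000, Y = 20000),
                    sdr_span = region("Y", 0, 10000),
                    par_span = region("Y", 10000, 20000),
                    n_gametologs = 2, n_par_pairs = 1,
                    theta_by_region = c(X = 0.004))
  v <- simulate_population_vcf(cfg)
  ac <- vcf_allele_counts(c(v, list()))
  wd <- windowed_diversity(ac, 10000, c(X = 600000))
  d <- wd$tajimas_d[!is.na(wd$tajimas_d)]
  expect_gte(length(d), 50)
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)) + 0.15)
  expect_true(all(wd$pi >= 0))
  expect_true(all(wd$S >= 0))
  expect_true(all(is.na(wd$tajimas_d) == (wd$S == 0)))
})

test_that("hudson fst matches explicit summation and limiting cases", {
  # identical frequencies, monomorphic variance-free case
  n <- 50
  f0 <- hudson_fst(c(25, 10), n, c(25, 10), n)
  expect_lte(f0$fst, 0 + 1e-9)
  # fixed difference with large n approaches 1
  f1 <- hudson_fst(rep(1000, 5), 1000, rep(0, 5), 1000)
  expect_equal(f1$fst, 1, tolerance = 1e-2)
  # oracle equivalence on random frequency regimes
  set.seed(31)
  for (rep_i in 1:20) {
    S <- sample(5:40, 1)
    n1 <- sample(10:30, 1); n2 <- sample(10:30, 1)
    c1 <- rbinom(S, n1, runif(S, 0.1, 0.9))
    c2 <- rbinom(S, n2, runif(S, 0.1, 0.9))
    got <- hudson_fst(c1, n1, c2, n2)
    expect_equal(got$fst, oracle_hudson_fst(c1, rep(n1, S), c2, rep(n2, S)),
                 tolerance = 1e-12)
  }
  expect_error(hudson_fst(1, 1, 1, 1), "called haplotypes")
})

test_that("the X-vs-Y contrast reports counts, densities and ratios", {
  sx <- list(counts = c(SNP = 100, insertion = 10, deletion = 10, other = 0),
             total = 120, density_per_kb = 12, mean_pi = 0.0034)
  sy <- list(counts = c(SNP = 50, insertion = 5, deletion = 5, other = 0),
             total = 60, density_per_kb = 6, mean_pi = 0.0008)
  tab <- contrast_references(sx, sy)
  expect_equal(tab$ratio_X_over_Y[tab$quantity == "total"], 2)
  expect_equal(tab$ratio_X_over_Y[tab$quantity == "mean_pi"], 4.25)
  same <- contrast_references(sx, sx)
  expect_true(all(same$ratio_X_over_Y[!is.na(same$ratio_X_over_Y)] == 1))
  expect_error(contrast_references(sx, list(total = 0)), "non-empty")
})
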
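# Simulation configuration: a toy genome with autosome(s), an X, and a Y
# carrying a hemizygous SDR plus a shared PAR, mirroring the study design of
# a dioecious hemp genome surveyed with 50+50 male/female pools.

#' Simulation configuration
#'
#' Defines the toy sex-chromosome system every simulator operation draws
#' from. Defaults give a desk-scale genome (100 kb autosome, 80 kb X, 60 kb Y
#' with a 40 kb SDR and 20 kb PAR), 150 gametolog pairs at mean true Ks 0.46,
#' 40x pools, and diversity 0.0034 (X) vs 0.0008 (Y-SDR).
#'
#' @param seed Integer master seed; all operations derive sub-streams from it.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param sdr_span,par_span [region()]s on the Y chromosome, 0-based
#'   half-open, disjoint.
#' @param n_gametologs Number of X/Y gametolog pairs in the SDR.
#' @param n_x_specific,n_y_specific Unpaired gene counts in the X-counterpart
#'   and Y-SDR.
#' @param n_par_pairs Gametolog pairs in the PAR (essentially undiverged).
#' @param true_ks Mean target synonymous divergence across SDR pairs.
#' @param ks_sd Spread of per-pair true Ks around `true_ks`.
#' @param true_ka Target nonsynonymous divergence (default mild purifying
#'   regime).
#' @param pool_depth Mean autosomal depth per pool (reads/bp).
#' @param leak Residual female-pool depth over the SDR as a fraction of
#'   `pool_depth` (mismapping noise).
#' @param inversion_spec List of `c(start, end)` anchor-index runs to reverse
#'   in the Y order.
#' @param theta_by_region Named numeric vector of expected per-site diversity;
#'   names are chromosome names or `"SDR"` / `"PAR"`.
#' @param n_haplotypes Even number of haplotypes for VCF simulation (>= 4).
#' @param indel_fraction Fraction of simulated variants that are short indels.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(A1 = 100000, X = 80000, Y = 60000),
                       sdr_span = region("Y", 0, 40000),
                       par_span = region("Y", 40000, 60000),
                       n_gametologs = 150L,
                       n_x_specific = 34L,
                       n_y_specific = 19L,
                       n_par_pairs = 20L,
                       true_ks = 0.46,
                       ks_sd = 0.1,
                       true_ka = 0.05,
                       pool_depth = 40,
                       leak = 0.02,
                       inversion_spec = NULL,
                       theta_by_region = c(X = 0.0034, SDR = 0.0008),
                       n_haplotypes = 20L,
                       indel_fraction = 0.13) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  for (sp in list(sdr_span, par_span)) {
    if (!inherits(sp, "region")) stop("sdr_span and par_span must be region()s")
    len <- chrom_lengths[sp$chrom]
    if (is.na(len) || sp$end > len)
      stop("span [", sp$start, ", ", sp$end, ") on ", sp$chrom,
           " exceeds its chromosome length")
  }
  if (regions_overlap(sdr_span, par_span))
    stop("sdr_span [", sdr_span$start, ", ", sdr_span$end,
         ") overlaps par_span [", par_span$start, ", ", par_span$end, ")")
  if (!(true_ks > 0 && true_ks < 0.75))
    stop("true_ks must lie in (0, 0.75), below Jukes-Cantor saturation")
  if (pool_depth <= 0) stop("pool_depth must be positive")
  if (leak < 0 || leak >= 1) stop("leak must lie in [0, 1)")
  if (any(theta_by_region < 0 | theta_by_region >= 0.1))
    stop("theta values must lie in [0, 0.1)")
  n_haplotypes <- as.integer(n_haplotypes)
  if (n_haplotypes < 4L) stop("n_haplotypes must be >= 4")
  if (n_haplotypes %% 2L != 0L)
    stop("n_haplotypes must be even (haplotypes are paired into diploids)")
  n_gametologs <- as.integer(n_gametologs)
  if (is.null(inversion_spec)) {
    # two reversed runs splitting the anchor set at ~43%, the structure the
    # detector is designed for, scaled to the configured pair count
    k <- max(1L, as.integer(round(0.433 * n_gametologs)))
    inversion_spec <- if (n_gametologs >= 4L)
      list(c(1L, k), c(k + 1L, n_gametologs)) else list()
  }
  for (run in inversion_spec) {
    if (length(run) != 2L || run[1] > run[2])
      stop("inversion_spec runs must be c(start, end) with start <= end")
    if (run[1] < 1L || run[2] > n_gametologs)
      stop("inversion_spec run [", run[1], ", ", run[2],
           "] outside [1, ", n_gametologs, "]")
  }
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 sdr_span = sdr_span, par_span = par_span,
                 n_gametologs = n_gametologs,
                 n_x_specific = as.integer(n_x_specific),
                 n_y_specific = as.integer(n_y_specific),
                 n_par_pairs = as.integer(n_par_pairs),
                 true_ks = true_ks, ks_sd = ks_sd, true_ka = true_ka,
                 pool_depth = pool_depth, leak = leak,
                 inversion_spec = inversion_spec,
                 theta_by_region = theta_by_region,
                 n_haplotypes = n_haplotypes,
                 indel_fraction = indel_fraction),
            class = "sim_config")
}
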
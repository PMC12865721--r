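# Pooled-sequencing depth simulation: female and male pools share the mean
# autosomal depth; over the hemizygous SDR the male pool drops to half and
# the female pool to a small mismapping leak. Per-window depth is Poisson.

#' Simulate windowed pool depth for a female and a male pool
#'
#' Windows tile every chromosome (last window may be short). Window means are
#' `pool_depth` everywhere except over the SDR, where the male pool has mean
#' `pool_depth / 2` (one Y copy) and the female pool `pool_depth * leak`
#' (mismapping background). Windows straddling an SDR boundary use the
#' overlap-weighted mean. Depths are independent Poisson draws per window.
#'
#' @param truth Truth list from [simulate_sex_genome()] (only `sdr_truth` is
#'   used), or a [region()] giving the SDR.
#' @param config A [sim_config()].
#' @param window Window size in bp (default 1000).
#' @return List with `female` and `male` [depth_track()] data frames.
#' @export
simulate_pool_depth <- function(truth, config, window = 1000) {
  stopifnot(inherits(config, "sim_config"))
  sdr <- if (inherits(truth, "region")) truth else truth$sdr_truth
  cl <- config$chrom_lengths
  if (window > max(cl)) stop("window larger than every chromosome")
  grid <- window_grid(cl, window)
  ov <- pmax(0, pmin(grid$end, sdr$end) - pmax(grid$start, sdr$start))
  frac <- ifelse(grid$chrom == sdr$chrom, ov / (grid$end - grid$start), 0)
  mean_f <- config$pool_depth * ((1 - frac) + frac * config$leak)
  mean_m <- config$pool_depth * ((1 - frac) + frac * 0.5)
  with_seed(sub_seed(config$seed, 3L), {
    female <- depth_track(grid$chrom, grid$start, grid$end,
                          stats::rpois(nrow(grid), mean_f), "female_pool")
    male <- depth_track(grid$chrom, grid$start, grid$end,
                        stats::rpois(nrow(grid), mean_m), "male_pool")
    list(female = female, male = male)
  })
}

# tiling windows over named chromosome lengths, 0-based half-open
window_grid <- function(chrom_lengths, window) {
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = window)
    data.frame(chrom = ch, start = starts, end = pmin(starts + window, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
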
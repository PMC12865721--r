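# Outlier filtering of Ks distributions and molecular-clock dating.

#' Tukey-fence outlier removal for Ks values
#'
#' Saturated (`NA`) estimates are dropped first, then values outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`. With fewer than 4 finite values the input
#' passes through unchanged with a warning.
#'
#' @param ks_values Numeric vector; `NA` marks saturated estimates.
#' @param ids Optional identifiers (defaults to `names(ks_values)`).
#' @param k Fence multiplier, default 1.5.
#' @return List with `values` (kept, named if ids available), `dropped_ids`,
#'   and `fences`.
#' @export
remove_outliers <- function(ks_values, ids = names(ks_values), k = 1.5) {
  if (is.null(ids)) ids <- as.character(seq_along(ks_values))
  stopifnot(length(ids) == length(ks_values))
  finite <- is.finite(ks_values)
  vals <- ks_values[finite]
  vids <- ids[finite]
  if (length(vals) < 4L) {
    warning("fewer than 4 finite Ks values; outlier filter skipped")
    return(list(values = stats::setNames(vals, vids),
                dropped_ids = ids[!finite], fences = c(NA_real_, NA_real_)))
  }
  q <- stats::quantile(vals, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - k * iqr, q[2] + k * iqr)
  keep <- vals >= fences[1] & vals <= fences[2]
  list(values = stats::setNames(vals[keep], vids[keep]),
       dropped_ids = c(ids[!finite], vids[!keep]),
       fences = fences)
}

#' Molecular clock model
#'
#' Either a direct per-lineage synonymous substitution rate (`rate` mode,
#' substitutions per synonymous site per year) or a calibration pair
#' (`calibration` mode) from which `lambda = ks_cal / (2 * t_cal)`.
#'
#' @param rate Substitution rate lambda (per site per year).
#' @param calibration_age Calibration divergence age in years.
#' @param calibration_ks Synonymous distance at the calibration age.
#' @return A `clock_model` list with `mode` and `lambda`.
#' @export
clock_model <- function(rate = NULL, calibration_age = NULL,
                        calibration_ks = NULL) {
  if (!is.null(rate)) {
    if (!is.null(calibration_age) || !is.null(calibration_ks))
      stop("supply either a rate or a calibration pair, not both")
    if (rate <= 0) stop("rate must be positive")
    return(structure(list(mode = "rate", lambda = rate), class = "clock_model"))
  }
  if (is.null(calibration_age) || is.null(calibration_ks))
    stop("calibration mode needs both calibration_age and calibration_ks")
  if (calibration_age <= 0 || calibration_ks <= 0)
    stop("calibration values must be positive")
  structure(list(mode = "calibration",
                 lambda = calibration_ks / (2 * calibration_age),
                 t_cal = calibration_age, ks_cal = calibration_ks),
            class = "clock_model")
}

#' Date a divergence from a Ks distribution
#'
#' `T = mean(Ks) / (2 * lambda)`; the 95% CI maps the normal-approximation
#' interval on mean Ks through the clock and is floored at zero.
#'
#' @param ks_values Filtered finite Ks values.
#' @param clock A [clock_model()].
#' @return A `divergence_date` list: `mean_ks`, `se_ks`, `n`, `lambda`,
#'   `t_years`, `ci95_years` (length-2), plus the same in Myr
#'   (`t_mya`, `ci95_mya`).
#' @export
date_divergence <- function(ks_values, clock) {
  stopifnot(inherits(clock, "clock_model"))
  vals <- ks_values[is.finite(ks_values)]
  if (!length(vals)) stop("no finite Ks values to date")
  if (clock$lambda <= 0) stop("clock rate must be positive")
  m <- mean(vals)
  se <- if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else 0
  t_years <- m / (2 * clock$lambda)
  ci_ks <- c(m - 1.96 * se, m + 1.96 * se)
  ci <- pmax(ci_ks, 0) / (2 * clock$lambda)
  structure(list(mean_ks = m, se_ks = se, n = length(vals),
                 lambda = clock$lambda,
                 t_years = t_years, ci95_years = ci,
                 t_mya = t_years / 1e6, ci95_mya = ci / 1e6),
            class = "divergence_date")
}

#' @export
print.divergence_date <- function(x, ...) {
  cat(sprintf(
    "X-Y divergence: %.1f Mya (95%% CI %.1f-%.1f), mean Ks = %.3f (n = %d, lambda = %.3g /site/yr)\n",
    x$t_mya, x$ci95_mya[1], x$ci95_mya[2], x$mean_ks, x$n, x$lambda))
  invisible(x)
}
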
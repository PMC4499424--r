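#' Fit a calibration curve
#'
#' Least-squares linear regression of detector response (peak-area ratio
#' of analyte to internal standard) on nominal concentration, optionally
#' weighted by 1/x or 1/x^2 — the usual choices when the calibration
#' range spans two orders of magnitude. A curve built on fewer than six
#' distinct levels is flagged as not reportable (the reference design
#' used at least nine).
#'
#' @param batch data frame with columns `level` (ng/mL, > 0) and
#'   `response` (area ratio), e.g. from [simulate_calibration_batch()].
#' @param weighting `"none"` (default), `"1/x"` or `"1/x2"`.
#' @return An object of class `calibration_curve`: `slope`, `intercept`,
#'   `r_squared`, `weighting`, `levels_used`, `reportable`.
#' @export
fit_calibration <- function(batch, weighting = c("none", "1/x", "1/x2")) {
  weighting <- match.arg(weighting)
  if (!all(c("level", "response") %in% names(batch)))
    stop("`batch` needs columns `level` and `response`")
  if (length(unique(batch$level)) < 2L)
    stop("calibration needs >= 2 distinct levels")
  if (any(batch$level <= 0)) stop("calibration levels must be > 0")
  w <- switch(weighting,
              "none" = rep(1, nrow(batch)),
              "1/x"  = 1 / batch$level,
              "1/x2" = 1 / batch$level^2)
  fit <- stats::lm(response ~ level, data = batch, weights = w)
  # weighted r2 computed directly (summary.lm warns on an exact fit)
  rss <- sum(w * stats::resid(fit)^2)
  tss <- sum(w * (batch$response - stats::weighted.mean(batch$response, w))^2)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = 1 - rss / tss,
         weighting = weighting,
         levels_used = sort(unique(batch$level)),
         reportable = length(unique(batch$level)) >= 6L),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve: y = %.6g x %+.6g (r2 = %.6f, weighting %s)\n",
              x$slope, x$intercept, x$r_squared, x$weighting))
  cat(sprintf("  %d levels, %.4g-%.4g ng/mL%s\n", length(x$levels_used),
              min(x$levels_used), max(x$levels_used),
              if (x$reportable) "" else "  [fewer than 6 levels: not reportable]"))
  invisible(x)
}

#' Back-calculate a concentration from a response ratio
#'
#' Inverts the calibration line and applies the dilution factor:
#' `((response - intercept) / slope) * dilution_factor`. Above-range
#' samples assayed after 10-fold dilution use `dilution_factor = 10`.
#' Negative back-calculated values are returned but flagged non-physical
#' with a warning.
#'
#' @param curve a [fit_calibration()] result (slope must be > 0).
#' @param response response ratio(s).
#' @param dilution_factor dilution applied before assay (>= 1).
#' @return Concentration(s) in ng/mL.
#' @export
back_calculate <- function(curve, response, dilution_factor = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop("calibration slope must be > 0")
  if (dilution_factor < 1) stop("`dilution_factor` must be >= 1")
  conc <- (response - curve$intercept) / curve$slope * dilution_factor
  if (any(conc < 0))
    warning("back-calculated concentration below zero: non-physical")
  conc
}

#' Limit of detection from signal-to-noise ratios
#'
#' The LOD is the lowest tested concentration whose signal-to-noise
#' ratio reaches the threshold (3:1 by convention). Selection is discrete
#' among the tested levels; no interpolation is attempted.
#'
#' @param series data frame with columns `concentration` (ng/mL, > 0),
#'   `signal` (peak response) and `noise` (baseline SD-equivalent, > 0).
#' @param ratio_threshold minimum acceptable S/N (default 3).
#' @return The LOD in ng/mL, or `NA` (with a message) if no level
#'   qualifies.
#' @export
lod_from_snr <- function(series, ratio_threshold = 3) {
  req <- c("concentration", "signal", "noise")
  if (!all(req %in% names(series)))
    stop("`series` needs columns concentration, signal, noise")
  if (nrow(series) < 1L) stop("`series` must have >= 1 level")
  if (any(series$noise <= 0)) stop("noise must be > 0")
  if (any(series$concentration <= 0)) stop("concentrations must be > 0")
  ok <- series$signal / series$noise >= ratio_threshold
  if (!any(ok)) {
    message("no tested level reaches S/N ", ratio_threshold,
            ": LOD not determined")
    return(NA_real_)
  }
  min(series$concentration[ok])
}

#' Limit of quantification from accuracy and precision criteria
#'
#' The LOQ is the lowest tested level determined both accurately
#' (relative error strictly below `re_limit`) and precisely (RSD strictly
#' below `rsd_limit`); 20% for both by convention. Strict inequalities:
#' a level sitting exactly on a limit fails.
#'
#' @param rows data frame with columns `level` (ng/mL), `re_pct` and
#'   `rsd_pct`, e.g. a [intraday_table()] result.
#' @param re_limit relative-error limit in percent (default 20).
#' @param rsd_limit RSD limit in percent (default 20).
#' @return The LOQ in ng/mL, or `NA` (with a message) if no level
#'   qualifies.
#' @export
loq_from_criteria <- function(rows, re_limit = 20, rsd_limit = 20) {
  req <- c("level", "re_pct", "rsd_pct")
  if (!all(req %in% names(rows)))
    stop("`rows` needs columns level, re_pct, rsd_pct")
  ok <- rows$re_pct < re_limit & rows$rsd_pct < rsd_limit
  if (!any(ok)) {
    message("no tested level meets RE < ", re_limit, "% and RSD < ",
            rsd_limit, "%: LOQ not determined")
    return(NA_real_)
  }
  min(rows$level[ok])
}
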
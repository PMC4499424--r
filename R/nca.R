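#' Terminal-phase log-linear regression
#'
#' Estimates the terminal elimination rate constant (lambda_z, the
#' pharmacokinetic K) by ordinary least squares of ln(concentration) on
#' time. With `window = NULL` the window is chosen automatically: every
#' suffix of at least three usable points that excludes the global
#' concentration maximum is fitted and the window with the highest
#' adjusted r-squared wins, ties broken toward more points — the de-facto
#' pharmacometric convention. A manual window `c(t_start, t_end)`
#' overrides the search.
#'
#' Below-quantification and non-positive concentrations never enter the
#' regression. A non-negative fitted slope yields a warning and an
#' unestimable (NA) lambda_z.
#'
#' @param profile a [conc_profile()].
#' @param window `NULL` for automatic selection, or `c(t_start, t_end)`
#'   in hours selecting observations with `t_start <= t <= t_end`.
#' @return An object of class `terminal_fit`: `lambda_z` (1/h),
#'   `intercept_log` (ln ng/mL at t = 0 of the terminal line),
#'   `n_points`, `window`, `r_squared`, `adjusted_r_squared`.
#' @export
fit_terminal_phase <- function(profile, window = NULL) {
  pts <- usable_points(profile)
  if (!is.null(window)) {
    if (length(window) != 2L || window[1] >= window[2])
      stop("`window` must be c(t_start, t_end) with t_start < t_end")
    sel <- pts$time >= window[1] & pts$time <= window[2]
    if (sum(sel) < 3L)
      stop("terminal fit needs >= 3 usable positive points in the window")
    return(ols_terminal(pts$time[sel], pts$conc[sel]))
  }
  n <- nrow(pts)
  if (n < 3L)
    stop("terminal fit needs >= 3 usable positive points")
  peak <- which.max(pts$conc)
  if (peak + 1L <= n - 2L) {
    starts <- seq(peak + 1L, n - 2L)
  } else if (peak <= n - 2L) {
    # too few points strictly after the peak (e.g. a 3-point monotone
    # decline): allow the window to begin at the peak itself
    starts <- seq(peak, n - 2L)
  } else {
    stop("too few points after the peak for a terminal fit")
  }
  fits <- lapply(starts, function(s) ols_terminal(pts$time[s:n], pts$conc[s:n]))
  adj <- vapply(fits, function(f)
    if (is.na(f$lambda_z)) -Inf else f$adjusted_r_squared, numeric(1))
  if (all(!is.finite(adj))) {
    warning("no window gives a declining terminal phase; lambda_z unestimable")
    return(fits[[1L]])
  }
  # ties (within numerical noise) resolved toward the longer window
  cand <- which(adj >= max(adj) - 1e-9)
  fits[[min(cand)]]
}

ols_terminal <- function(t, c) {
  fit <- stats::lm(log(c) ~ t)
  slope <- unname(stats::coef(fit)[2])
  y <- log(c)
  n <- length(t)
  # r2 computed directly so an exact fit does not trip summary.lm's
  # perfect-fit warning
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj <- if (is.na(r2)) NA_real_ else 1 - (1 - r2) * (n - 1) / (n - 2)
  out <- structure(
    list(lambda_z = -slope,
         intercept_log = unname(stats::coef(fit)[1]),
         n_points = n,
         window = c(min(t), max(t)),
         r_squared = r2,
         adjusted_r_squared = adj),
    class = "terminal_fit"
  )
  # a slope indistinguishable from zero is a flat, not declining, phase
  if (!is.finite(slope) || slope >= -1e-10) {
    warning("terminal slope is not negative; lambda_z unestimable")
    out$lambda_z <- NA_real_
  }
  out
}

#' @export
print.terminal_fit <- function(x, ...) {
  cat(sprintf(
    "Terminal fit: lambda_z = %s 1/h over [%g, %g] h (%d points, adj r2 = %.4f)\n",
    if (is.na(x$lambda_z)) "NA" else sprintf("%.5g", x$lambda_z),
    x$window[1], x$window[2], x$n_points, x$adjusted_r_squared))
  invisible(x)
}

#' Elimination half-life
#'
#' `0.693 / lambda_z`. The literal constant 0.693 (rather than ln 2 =
#' 0.693147...) is used deliberately, matching the conventional reporting
#' formula; the relative difference is below 0.03%.
#'
#' @param lambda_z terminal rate constant, 1/h, > 0.
#' @return Half-life in hours.
#' @export
half_life <- function(lambda_z) {
  if (any(!is.finite(lambda_z)) || any(lambda_z <= 0))
    stop("`lambda_z` must be > 0")
  0.693 / lambda_z
}

#' Trapezoidal area under a curve
#'
#' Linear rule: \eqn{\sum (t_2-t_1)(C_1+C_2)/2}. The
#' `"linear-up/log-down"` variant replaces each strictly declining
#' segment with \eqn{(t_2-t_1)(C_1-C_2)/\ln(C_1/C_2)} (exact for
#' exponential decline) when both endpoints are positive, and falls back
#' to the linear rule otherwise.
#'
#' @param times strictly increasing times (>= 2 points).
#' @param concentrations non-negative values, same length.
#' @param method `"linear"` (default) or `"linear-up/log-down"`.
#' @return The area, in concentration x time units of the inputs.
#' @export
auc_trapezoid <- function(times, concentrations,
                          method = c("linear", "linear-up/log-down")) {
  method <- match.arg(method)
  n <- length(times)
  if (n < 2L || length(concentrations) != n)
    stop("need >= 2 points with matching lengths")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  dt <- diff(times)
  c1 <- concentrations[-n]
  c2 <- concentrations[-1]
  seg <- dt * (c1 + c2) / 2
  if (method == "linear-up/log-down") {
    logdown <- c1 > c2 & c2 > 0
    seg[logdown] <- dt[logdown] * (c1[logdown] - c2[logdown]) /
      log(c1[logdown] / c2[logdown])
  }
  sum(seg)
}

#' Extrapolated AUC tail beyond the last observation
#'
#' `c_last / lambda_z`, the area of the terminal mono-exponential from
#' the last quantifiable concentration to infinity.
#'
#' @param c_last last quantifiable concentration (> 0; a zero value
#'   returns 0 with a warning since no extrapolation is possible).
#' @param lambda_z terminal rate constant, 1/h, > 0.
#' @return Tail area in the concentration x time units of `c_last`.
#' @export
auc_extrapolated_tail <- function(c_last, lambda_z) {
  if (!is.finite(lambda_z) || lambda_z <= 0) stop("`lambda_z` must be > 0")
  if (!is.finite(c_last) || c_last < 0) stop("`c_last` must be >= 0")
  if (c_last == 0) {
    warning("c_last is 0: no extrapolation possible, tail area 0")
    return(0)
  }
  c_last / lambda_z
}

#' Area under the first-moment curve to infinity
#'
#' Trapezoidal area of C x t versus t over the observed range, plus the
#' analytic tail `c_last*t_last/lambda_z + c_last/lambda_z^2`.
#'
#' @inheritParams auc_trapezoid
#' @param c_last,t_last last quantifiable concentration and its time
#'   (default: last elements of the inputs).
#' @param lambda_z terminal rate constant, 1/h.
#' @return AUMC from zero to infinity, concentration x time^2 units.
#' @export
aumc_inf <- function(times, concentrations,
                     c_last = concentrations[length(concentrations)],
                     t_last = times[length(times)],
                     lambda_z,
                     method = c("linear", "linear-up/log-down")) {
  observed <- auc_trapezoid(times, times * concentrations, match.arg(method))
  observed + aumc_tail(c_last, t_last, lambda_z)
}

aumc_tail <- function(c_last, t_last, lambda_z) {
  if (c_last == 0) return(0)
  c_last * t_last / lambda_z + c_last / lambda_z^2
}

#' Mean residence time
#'
#' @param aumc area under the first-moment curve (concentration x h^2).
#' @param auc area under the curve to infinity (concentration x h), > 0.
#' @return MRT in hours.
#' @export
mrt <- function(aumc, auc) {
  if (!is.finite(auc) || auc <= 0) stop("`auc` must be > 0")
  aumc / auc
}

#' Systemic clearance
#'
#' Dose divided by AUC0-inf. With dose in ug/kg and AUC in ug.h/mL the
#' result is in mL per kg per h.
#'
#' @param dose dose in ug/kg, > 0.
#' @param auc_inf AUC from zero to infinity in ug.h/mL, > 0.
#' @return Clearance in mL kg^-1 h^-1.
#' @export
clearance <- function(dose, auc_inf) {
  if (!is.finite(dose) || dose <= 0) stop("`dose` must be > 0")
  if (!is.finite(auc_inf) || auc_inf <= 0) stop("`auc_inf` must be > 0")
  dose / auc_inf
}

#' Steady-state volume of distribution
#'
#' Two conventions are provided. `mode = "paper"` computes `cl / mrt`,
#' the relation used by the reference report (whose printed Vss is
#' numerically Cl/MRT even though the quotient is dimensionally a
#' clearance per time); `mode = "conventional"` computes the standard
#' `cl * mrt`. The result carries its mode as attribute `"mode"`.
#'
#' @param cl clearance, mL kg^-1 h^-1, > 0.
#' @param mrt mean residence time, h, > 0.
#' @param mode `"paper"` (default) or `"conventional"`.
#' @return Volume in mL/kg, with attribute `mode`.
#' @export
vss <- function(cl, mrt, mode = c("paper", "conventional")) {
  mode <- match.arg(mode)
  if (!is.finite(cl) || cl <= 0) stop("`cl` must be > 0")
  if (!is.finite(mrt) || mrt <= 0) stop("`mrt` must be > 0")
  out <- if (mode == "paper") cl / mrt else cl * mrt
  attr(out, "mode") <- mode
  out
}

#' Noncompartmental analysis of one profile
#'
#' Orchestrates the full NCA of an IV-bolus profile: terminal log-linear
#' regression, trapezoidal AUC/AUMC with extrapolation to infinity,
#' half-life, MRT, clearance and both Vss conventions. Concentrations are
#' converted from ng/mL to ug/mL (divide by 1000) before integration so
#' AUC is reported in ug.h/mL and clearance in mL kg^-1 h^-1.
#'
#' For an IV bolus the concentration at t = 0 is back-extrapolated
#' (log-linearly through the first two usable points when they decline,
#' otherwise by carrying the first observation back) and prepended before
#' integration, unless the profile already starts at t = 0 or
#' `extrapolate_c0 = FALSE`.
#'
#' @param profile a [conc_profile()].
#' @param window terminal window passed to [fit_terminal_phase()].
#' @param method trapezoid method, `"linear"` (default) or
#'   `"linear-up/log-down"`.
#' @param vss_mode `"paper"` or `"conventional"` (see [vss()]).
#' @param extrapolate_c0 logical; back-extrapolate C0 for the bolus.
#' @return An object of class `nca_result` with fields `lambda_z` (1/h),
#'   `t_half` (h), `auc_last`, `auc_inf` (ug.h/mL), `aumc_inf`
#'   (ug.h^2/mL), `mrt` (h), `cl` (mL kg^-1 h^-1), `vss_paper`,
#'   `vss_conventional` (mL/kg), `pct_extrapolated` (%), plus the
#'   `terminal_fit`, the dose and the subject id. If lambda_z is
#'   unestimable every extrapolation-dependent field is NA.
#' @export
run_nca <- function(profile, window = NULL,
                    method = c("linear", "linear-up/log-down"),
                    vss_mode = c("paper", "conventional"),
                    extrapolate_c0 = TRUE) {
  method <- match.arg(method)
  vss_mode <- match.arg(vss_mode)
  stopifnot(inherits(profile, "conc_profile"))
  pts <- usable_points(profile)
  if (nrow(pts) < 3L)
    stop("NCA needs >= 3 usable positive observations")
  fit <- fit_terminal_phase(profile, window = window)

  t <- pts$time
  c_ug <- pts$conc / 1000            # ng/mL -> ug/mL
  if (extrapolate_c0 && t[1] > 0) {
    c0 <- backextrapolate_c0(t, c_ug)
    t <- c(0, t)
    c_ug <- c(c0, c_ug)
  }
  n <- length(t)
  auc_last <- auc_trapezoid(t, c_ug, method)
  c_last <- c_ug[n]
  t_last <- t[n]

  if (is.na(fit$lambda_z)) {
    warning("lambda_z unestimable: extrapolated quantities unavailable")
    res <- list(lambda_z = NA_real_, t_half = NA_real_, auc_last = auc_last,
                auc_inf = NA_real_, aumc_inf = NA_real_, mrt = NA_real_,
                cl = NA_real_, vss_paper = NA_real_,
                vss_conventional = NA_real_, pct_extrapolated = NA_real_)
  } else {
    lz <- fit$lambda_z
    auc_inf <- auc_last + auc_extrapolated_tail(c_last, lz)
    aumc <- aumc_inf(t, c_ug, c_last, t_last, lz, method)
    mrt_h <- mrt(aumc, auc_inf)
    cl_v <- clearance(profile$dose, auc_inf)
    res <- list(lambda_z = lz,
                t_half = half_life(lz),
                auc_last = auc_last,
                auc_inf = auc_inf,
                aumc_inf = aumc,
                mrt = mrt_h,
                cl = cl_v,
                vss_paper = as.numeric(vss(cl_v, mrt_h, "paper")),
                vss_conventional = as.numeric(vss(cl_v, mrt_h, "conventional")),
                pct_extrapolated = 100 * (auc_inf - auc_last) / auc_inf)
  }
  res$vss_mode <- vss_mode
  res$vss <- if (vss_mode == "paper") res$vss_paper else res$vss_conventional
  res$terminal_fit <- fit
  res$dose <- profile$dose
  res$subject_id <- profile$subject_id
  structure(res, class = "nca_result")
}

backextrapolate_c0 <- function(t, c) {
  if (length(c) >= 2L && c[1] > c[2] && c[2] > 0) {
    slope <- (log(c[2]) - log(c[1])) / (t[2] - t[1])
    exp(log(c[1]) - slope * t[1])
  } else {
    c[1]
  }
}

#' @export
print.nca_result <- function(x, ...) {
  cat("Noncompartmental analysis: subject", x$subject_id, "\n")
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4g", v)
  cat(sprintf("  lambda_z %s 1/h | t1/2 %s h | AUCinf %s ug.h/mL (%s%% extrapolated)\n",
              fmt(x$lambda_z), fmt(x$t_half), fmt(x$auc_inf),
              fmt(x$pct_extrapolated)))
  cat(sprintf("  MRT %s h | Cl %s mL/kg/h | Vss (%s) %s mL/kg\n",
              fmt(x$mrt), fmt(x$cl), x$vss_mode, fmt(x$vss)))
  invisible(x)
}

#' Cohort summary of NCA results
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' each pharmacokinetic parameter across subjects, in the conventional
#' reporting order (dose, AUC0-inf, K, t1/2, MRT, Cl, Vss). Parameters
#' are averaged per subject first; derived quantities are never
#' recomputed from averaged inputs.
#'
#' @param results non-empty list of [run_nca()] results.
#' @return Data frame with columns `parameter`, `unit`, `mean`, `sd`,
#'   `n`; `sd` is NA for a single subject.
#' @export
summarize_cohort <- function(results) {
  if (length(results) < 1L) stop("`results` must be a non-empty list")
  stopifnot(all(vapply(results, inherits, logical(1), "nca_result")))
  fields <- c(dose = "dose", auc_inf = "auc_inf", lambda_z = "lambda_z",
              t_half = "t_half", mrt = "mrt", cl = "cl", vss = "vss")
  units <- c("ug/kg", "ug.h/mL", "1/h", "h", "h", "mL/kg/h", "mL/kg")
  vals <- lapply(fields, function(f)
    vapply(results, function(r) as.numeric(r[[f]]), numeric(1)))
  data.frame(
    parameter = names(fields),
    unit = units,
    mean = vapply(vals, mean, numeric(1)),
    sd = vapply(vals, function(v)
      if (length(v) > 1L) stats::sd(v) else NA_real_, numeric(1)),
    n = length(results),
    row.names = NULL
  )
}
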
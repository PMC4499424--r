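#' Assay noise model
#'
#' Proportional + additive error on the concentration scale, the standard
#' bioanalytical measurement-error structure, plus a between-subject CV
#' applied multiplicatively to each subject's exponential coefficients.
#' With all three components zero the simulator returns the deterministic
#' model curve exactly.
#'
#' @param proportional_cv coefficient of variation of the proportional
#'   error component (fraction, >= 0).
#' @param additive_sd standard deviation of the additive component
#'   (ng/mL, >= 0).
#' @param inter_subject_cv between-subject CV of the disposition
#'   coefficients (fraction, >= 0).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(proportional_cv = 0, additive_sd = 0,
                        inter_subject_cv = 0) {
  vals <- c(proportional_cv, additive_sd, inter_subject_cv)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("noise components must be finite and >= 0")
  structure(list(proportional_cv = proportional_cv,
                 additive_sd = additive_sd,
                 inter_subject_cv = inter_subject_cv),
            class = "noise_model")
}

#' Assay quantification limits and dilution policy
#'
#' @param lloq lower limit of quantification, ng/mL.
#' @param uloq upper limit of quantification (top of the calibration
#'   range), ng/mL; samples above it are assayed after dilution.
#' @param dilution_factor dilution applied to above-range samples (> 1).
#' @return An object of class `assay_config`. Defaults describe a
#'   5-1000 ng/mL calibration range with 10-fold dilution.
#' @export
assay_config <- function(lloq = 5, uloq = 1000, dilution_factor = 10) {
  if (!(lloq > 0 && uloq > lloq))
    stop("need 0 < lloq < uloq")
  if (!(dilution_factor > 1))
    stop("`dilution_factor` must be > 1")
  structure(list(lloq = lloq, uloq = uloq,
                 dilution_factor = dilution_factor),
            class = "assay_config")
}

#' Linear detector response model
#'
#' Peak-area ratio (analyte / internal standard) as a linear function of
#' concentration, with proportional noise on the response. Defaults are
#' the reference assay's printed regression, y = 0.0015 x - 0.0087.
#'
#' @param slope response-ratio per ng/mL (> 0).
#' @param intercept response-ratio at zero concentration.
#' @param response_cv proportional CV of the response (fraction, >= 0).
#' @return An object of class `response_model`.
#' @export
response_model <- function(slope = 0.0015, intercept = -0.0087,
                           response_cv = 0) {
  if (!(slope > 0)) stop("`slope` must be > 0")
  if (response_cv < 0) stop("`response_cv` must be >= 0")
  structure(list(slope = slope, intercept = intercept,
                 response_cv = response_cv),
            class = "response_model")
}

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

simulate_conc <- function(mu, noise) {
  n <- length(mu)
  conc <- mu * (1 + stats::rnorm(n, 0, noise$proportional_cv)) +
    stats::rnorm(n, 0, noise$additive_sd)
  pmax(conc, 0)
}

#' Simulate one concentration-time profile
#'
#' Evaluates the disposition model at the schedule and perturbs each value
#' as `model * (1 + proportional deviate) + additive deviate`, truncated
#' below at zero. Deterministic for a fixed seed; with a zero noise model
#' the output equals [model_concentration()] at every time.
#'
#' @param params a [disposition_params()] object.
#' @param schedule sampling times in hours (default [default_schedule()]).
#' @param noise a [noise_model()].
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @param subject_id label for the simulated subject.
#' @return A [conc_profile()].
#' @export
simulate_profile <- function(params, schedule = default_schedule(),
                             noise = noise_model(), seed = NULL,
                             subject_id = "sim-1") {
  stopifnot(inherits(params, "disposition_params"),
            inherits(noise, "noise_model"))
  mu <- model_concentration(params, schedule)
  conc <- with_optional_seed(seed, simulate_conc(mu, noise))
  conc_profile(subject_id, params$dose, schedule, conc)
}

#' Simulate a cohort of subjects
#'
#' Each subject's exponential coefficients are jittered by a mean-one
#' lognormal factor with CV `inter_subject_cv` (rates are shared), then
#' per-sample assay noise is applied; subjects are independent.
#'
#' @inheritParams simulate_profile
#' @param n_subjects number of subjects (default 6, the reference cohort
#'   size).
#' @return List of [conc_profile()] objects with ids `"sim-1"`, ...
#' @export
simulate_cohort <- function(params, schedule = default_schedule(),
                            noise = noise_model(), n_subjects = 6,
                            seed = NULL) {
  stopifnot(inherits(params, "disposition_params"),
            inherits(noise, "noise_model"))
  if (n_subjects < 1) stop("`n_subjects` must be >= 1")
  # sdlog chosen so the lognormal factor has mean 1 and CV = inter_subject_cv
  sdlog <- sqrt(log(1 + noise$inter_subject_cv^2))
  with_optional_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      fac <- exp(stats::rnorm(1, -sdlog^2 / 2, sdlog))
      p_i <- disposition_params(params$coefficients * fac, params$rates,
                                params$dose)
      mu <- model_concentration(p_i, schedule)
      conc_profile(paste0("sim-", i), params$dose, schedule,
                   simulate_conc(mu, noise))
    })
  })
}

#' Apply quantification limits to a profile
#'
#' Flags values below the LLOQ as below-limit (value retained, marked
#' unusable) and values above the ULOQ as assayed by dilution (value
#' retained, provenance noted). Numeric values are never altered. The
#' count of usable (non-BLQ) records is attached as attribute
#' `n_usable`.
#'
#' @param profile a [conc_profile()].
#' @param assay an [assay_config()].
#' @return The flagged profile.
#' @export
apply_assay <- function(profile, assay = assay_config()) {
  stopifnot(inherits(profile, "conc_profile"), inherits(assay, "assay_config"))
  profile$blq <- profile$concentrations < assay$lloq
  profile$diluted <- profile$concentrations > assay$uloq
  attr(profile, "n_usable") <- sum(!profile$blq)
  profile
}

#' Simulate a calibration batch
#'
#' Response ratios at each calibration level: `slope * level + intercept`,
#' perturbed multiplicatively by `response_cv`. Default levels are the
#' reference assay's ten calibration standards spanning 5-1000 ng/mL.
#'
#' @param rm a [response_model()].
#' @param levels calibration levels in ng/mL (> 0).
#' @param replicates replicates per level.
#' @param seed optional integer seed.
#' @return Data frame with columns `level`, `replicate`, `response`.
#' @export
simulate_calibration_batch <- function(rm = response_model(),
                                       levels = c(5, 10, 20, 50, 70, 100,
                                                  200, 500, 700, 1000),
                                       replicates = 1, seed = NULL) {
  stopifnot(inherits(rm, "response_model"))
  if (any(levels <= 0)) stop("calibration levels must be > 0")
  if (replicates < 1) stop("`replicates` must be >= 1")
  grid <- expand.grid(replicate = seq_len(replicates), level = levels)
  mu <- rm$slope * grid$level + rm$intercept
  resp <- with_optional_seed(seed,
    mu * (1 + stats::rnorm(length(mu), 0, rm$response_cv)))
  data.frame(level = grid$level, replicate = grid$replicate,
             response = resp)
}

#' Simulate a quality-control batch
#'
#' Replicated QC measurements over days on the concentration scale:
#' `measured = level * (1 + day effect) * (1 + replicate effect)`, with the
#' day effect shared by all measurements of one day. Defaults follow the
#' reference design: QC levels 10/50/100/500/1000 ng/mL, five replicates
#' per day, three days.
#'
#' @param levels QC nominal levels in ng/mL.
#' @param replicates_per_day replicates of each level within a day.
#' @param days number of days.
#' @param intraday_cv within-day (replicate) CV, fraction.
#' @param interday_cv between-day CV, fraction.
#' @param seed optional integer seed.
#' @return A `qc_batch`: data frame with columns `level`, `day`,
#'   `replicate`, `value` (measured concentration, ng/mL).
#' @export
simulate_qc_batch <- function(levels = c(10, 50, 100, 500, 1000),
                              replicates_per_day = 5, days = 3,
                              intraday_cv = 0, interday_cv = 0,
                              seed = NULL) {
  if (any(levels <= 0)) stop("QC levels must be > 0")
  if (replicates_per_day < 1 || days < 1)
    stop("`replicates_per_day` and `days` must be >= 1")
  if (intraday_cv < 0 || interday_cv < 0) stop("CVs must be >= 0")
  with_optional_seed(seed, {
    day_eff <- stats::rnorm(days, 0, interday_cv)
    grid <- expand.grid(replicate = seq_len(replicates_per_day),
                        day = seq_len(days), level = levels)
    rep_eff <- stats::rnorm(nrow(grid), 0, intraday_cv)
    value <- grid$level * (1 + day_eff[grid$day]) * (1 + rep_eff)
    structure(data.frame(level = grid$level, day = grid$day,
                         replicate = grid$replicate, value = value),
              class = c("qc_batch", "data.frame"))
  })
}
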
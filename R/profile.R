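#' Concentration-time profile for one subject
#'
#' Container for one subject's IV-bolus plasma concentration-time record:
#' dose, strictly increasing sampling times (h), measured concentrations
#' (ng/mL) and per-sample flags. `blq` marks values below the lower limit
#' of quantification (retained but unusable for analysis); `diluted` marks
#' values above the upper limit that would be assayed after dilution
#' (retained, provenance noted).
#'
#' @param subject_id subject label (coerced to character).
#' @param dose dose in ug per kg body weight.
#' @param times numeric sampling times in hours, strictly increasing, >= 0.
#' @param concentrations numeric concentrations in ng/mL, >= 0, same length.
#' @param blq logical below-quantification flags (default all `FALSE`).
#' @param diluted logical dilution-assay flags (default all `FALSE`).
#' @return An object of class `conc_profile`.
#' @export
conc_profile <- function(subject_id, dose, times, concentrations,
                         blq = rep(FALSE, length(times)),
                         diluted = rep(FALSE, length(times))) {
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  if (length(times) != length(concentrations) ||
      length(times) != length(blq) || length(times) != length(diluted))
    stop("times, concentrations and flags must have equal length")
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and >= 0")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    stop("concentrations must be finite and >= 0")
  if (!is.numeric(dose) || length(dose) != 1L || dose <= 0)
    stop("`dose` must be a single positive number (ug/kg)")
  structure(
    list(subject_id = as.character(subject_id), dose = as.numeric(dose),
         times = times, concentrations = concentrations,
         blq = as.logical(blq), diluted = as.logical(diluted)),
    class = "conc_profile"
  )
}

#' Usable observations of a profile
#'
#' Observations not flagged below the quantification limit and with a
#' strictly positive concentration, i.e. the records that enter terminal
#' regression and AUC computation.
#'
#' @param profile a [conc_profile()] object.
#' @return Data frame with columns `time` and `conc`.
#' @export
usable_points <- function(profile) {
  stopifnot(inherits(profile, "conc_profile"))
  keep <- !profile$blq & profile$concentrations > 0
  data.frame(time = profile$times[keep], conc = profile$concentrations[keep])
}

#' @export
print.conc_profile <- function(x, ...) {
  cat("Concentration-time profile: subject", x$subject_id,
      "| dose", x$dose, "ug/kg |", length(x$times), "samples\n")
  print(data.frame(time_h = x$times, conc_ng_per_ml = signif(x$concentrations, 6),
                   blq = x$blq, diluted = x$diluted), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.conc_profile <- function(x, ...) {
  data.frame(subject_id = x$subject_id,
             dose_ug_per_kg = x$dose,
             time_h = x$times,
             conc_ng_per_ml = x$concentrations,
             blq_flag = x$blq,
             diluted_flag = x$diluted,
             stringsAsFactors = FALSE)
}
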
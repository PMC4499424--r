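#' Relative error (accuracy)
#'
#' `100 * |nominal - measured| / nominal`, the accuracy measure of
#' bioanalytical validation.
#'
#' @param nominal nominal concentration(s), > 0.
#' @param measured_mean measured mean concentration(s).
#' @return Relative error in percent.
#' @export
relative_error <- function(nominal, measured_mean) {
  if (any(!is.finite(nominal)) || any(nominal <= 0))
    stop("`nominal` must be > 0")
  100 * abs(nominal - measured_mean) / nominal
}

#' Relative standard deviation (precision)
#'
#' `100 * sample SD / mean` of replicate measurements (n - 1
#' denominator). [rsd_from_summary()] computes the same quantity from an
#' already-summarised mean and SD.
#'
#' @param measurements numeric vector of >= 2 replicates with positive
#'   mean.
#' @return RSD in percent.
#' @export
rsd <- function(measurements) {
  if (length(measurements) < 2L)
    stop("RSD needs >= 2 measurements")
  rsd_from_summary(mean(measurements), stats::sd(measurements))
}

#' @rdname rsd
#' @param mean,sd summary mean (> 0) and standard deviation.
#' @export
rsd_from_summary <- function(mean, sd) {
  if (any(!is.finite(mean)) || any(mean <= 0))
    stop("mean must be > 0")
  100 * sd / mean
}

validation_row_table <- function(batch) {
  levels <- sort(unique(batch$level))
  rows <- lapply(levels, function(lv) {
    x <- batch$value[batch$level == lv]
    if (length(x) < 2L) {
      warning("level ", lv, " has < 2 replicates: skipped")
      return(NULL)
    }
    data.frame(level = lv, n = length(x), measured_mean = mean(x),
               sd = stats::sd(x),
               rsd_pct = rsd(x),
               re_pct = relative_error(lv, mean(x)))
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Intra-day precision and accuracy table
#'
#' Per-level mean, SD, RSD% and RE% of one day's QC replicates, in the
#' conventional validation-table layout.
#'
#' @param batch a QC batch data frame with columns `level`, `day`,
#'   `replicate`, `value` (see [simulate_qc_batch()]).
#' @param day which day to summarise (default: the first day present).
#' @return Data frame with columns `level`, `n`, `measured_mean`, `sd`,
#'   `rsd_pct`, `re_pct`; levels with fewer than two replicates are
#'   skipped with a warning.
#' @export
intraday_table <- function(batch, day = NULL) {
  check_qc(batch)
  if (is.null(day)) day <- min(batch$day)
  sub <- batch[batch$day == day, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rows for day ", day)
  validation_row_table(sub)
}

#' Inter-day precision and accuracy table
#'
#' Per-level statistics pooled over all replicates of all days (a single
#' mean and SD per level, the layout of the conventional inter-day
#' block), rather than statistics of day means.
#'
#' @inheritParams intraday_table
#' @return As [intraday_table()].
#' @export
interday_table <- function(batch) {
  check_qc(batch)
  if (length(unique(batch$day)) < 2L)
    stop("inter-day statistics need >= 2 distinct days; use intraday_table()")
  validation_row_table(batch)
}

check_qc <- function(batch) {
  req <- c("level", "day", "replicate", "value")
  if (!all(req %in% names(batch)))
    stop("QC batch needs columns ", paste(req, collapse = ", "))
  if (any(batch$level <= 0)) stop("nominal levels must be > 0")
  invisible(batch)
}

#' Apply the 15/20 acceptance rule to validation rows
#'
#' A row passes when both RSD% and RE% are at most 15, except at the LOQ
#' level where the limit is 20 (values are rejected only when strictly
#' above the limit).
#'
#' @param rows a validation table ([intraday_table()] output).
#' @param loq_level the LOQ level in ng/mL (its row gets the 20% limit).
#' @param limit,loq_limit acceptance limits in percent (defaults 15, 20).
#' @return `rows` with columns `limit_pct` and `pass` appended.
#' @export
acceptance_flags <- function(rows, loq_level, limit = 15, loq_limit = 20) {
  if (!all(c("level", "rsd_pct", "re_pct") %in% names(rows)))
    stop("`rows` needs columns level, rsd_pct, re_pct")
  lim <- ifelse(rows$level == loq_level, loq_limit, limit)
  rows$limit_pct <- lim
  rows$pass <- rows$rsd_pct <= lim & rows$re_pct <= lim
  rows
}

#' Extraction recovery
#'
#' Mean response of processed (extracted) samples relative to the mean
#' response of unextracted reference standards, in percent. The SD is
#' that of the individual processed-replicate ratios against the
#' reference mean.
#'
#' @param processed_responses responses of extracted replicates.
#' @param reference_responses responses of reference standards (positive
#'   mean).
#' @return List with `recovery_pct`, `sd_pct` and the replicate counts.
#' @export
recovery <- function(processed_responses, reference_responses) {
  if (length(processed_responses) < 1L || length(reference_responses) < 1L)
    stop("both response vectors must be non-empty")
  ref_mean <- mean(reference_responses)
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop("reference mean response must be > 0")
  ratios <- 100 * processed_responses / ref_mean
  list(recovery_pct = mean(ratios),
       sd_pct = if (length(ratios) > 1L) stats::sd(ratios) else NA_real_,
       n_processed = length(processed_responses),
       n_reference = length(reference_responses))
}

#' Stability table
#'
#' Percent of analyte remaining under each storage condition relative to
#' the initial (or nominal) concentration; a sample is stable when the
#' deviation from 100% is at most 5 percentage points.
#'
#' @param measured data frame with columns `condition` (label), `level`
#'   (ng/mL) and `measured` (ng/mL).
#' @param reference reference concentration per level: either a single
#'   number, or a named numeric vector keyed by level (as character).
#' @param tolerance_pct allowed deviation from 100% (default 5).
#' @return Data frame with columns `condition`, `level`, `pct_remained`,
#'   `stable`.
#' @export
stability_rows <- function(measured, reference, tolerance_pct = 5) {
  req <- c("condition", "level", "measured")
  if (!all(req %in% names(measured)))
    stop("`measured` needs columns condition, level, measured")
  ref <- if (length(reference) == 1L && is.null(names(reference))) {
    rep(as.numeric(reference), nrow(measured))
  } else {
    as.numeric(reference[as.character(measured$level)])
  }
  if (any(!is.finite(ref)) || any(ref <= 0))
    stop("reference concentrations must be > 0 for every level")
  pct <- 100 * measured$measured / ref
  data.frame(condition = measured$condition,
             level = measured$level,
             pct_remained = pct,
             stable = abs(100 - pct) <= tolerance_pct)
}
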
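PROFILE_COLS <- c("subject_id", "dose_ug_per_kg", "time_h",
                  "conc_ng_per_ml", "blq_flag", "diluted_flag")

#' Write concentration-time profiles to delimited text
#'
#' Comma-separated, header row, UTF-8, "." decimal; columns
#' `subject_id, dose_ug_per_kg, time_h, conc_ng_per_ml, blq_flag,
#' diluted_flag`. Full precision is written; rounding is display-only
#' elsewhere.
#'
#' @param profiles a [conc_profile()] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "conc_profile")) profiles <- list(profiles)
  tab <- do.call(rbind, lapply(profiles, as.data.frame))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read concentration-time profiles from delimited text
#'
#' Validates the on-disk table (written by [write_profiles()]) and
#' rebuilds one [conc_profile()] per subject. Malformed content —
#' missing columns, non-increasing times, negative concentrations — is
#' reported as an error naming the offending subject or column.
#'
#' @param path input file path.
#' @return List of [conc_profile()] objects, in file order of subjects.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty input: ", path, " contains no records")
  missing <- setdiff(PROFILE_COLS, names(tab))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  if (any(!is.finite(tab$conc_ng_per_ml) | tab$conc_ng_per_ml < 0)) {
    bad <- which(!is.finite(tab$conc_ng_per_ml) | tab$conc_ng_per_ml < 0)[1]
    stop("negative or non-numeric concentration at data row ", bad,
         " (subject ", tab$subject_id[bad], ")")
  }
  ids <- unique(tab$subject_id)
  lapply(ids, function(id) {
    sub <- tab[tab$subject_id == id, , drop = FALSE]
    if (any(diff(sub$time_h) <= 0))
      stop("times not strictly increasing for subject ", id)
    if (length(unique(sub$dose_ug_per_kg)) != 1L)
      stop("inconsistent dose for subject ", id)
    conc_profile(id, sub$dose_ug_per_kg[1], sub$time_h, sub$conc_ng_per_ml,
                 as.logical(sub$blq_flag), as.logical(sub$diluted_flag))
  })
}

#' Write / read a QC or calibration batch
#'
#' Delimited text with columns `level_ng_per_ml, day, replicate, value`.
#'
#' @param batch data frame with columns `level`, `day`, `replicate`,
#'   `value` (a calibration batch may use `response` in place of `value`;
#'   `day` defaults to 1 if absent).
#' @param path file path.
#' @return `path` invisibly (write); the batch data frame (read).
#' @export
write_qc_batch <- function(batch, path) {
  if (!"value" %in% names(batch) && "response" %in% names(batch))
    batch$value <- batch$response
  if (!"day" %in% names(batch)) batch$day <- 1L
  out <- data.frame(level_ng_per_ml = batch$level, day = batch$day,
                    replicate = batch$replicate, value = batch$value)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_qc_batch
#' @export
read_qc_batch <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("level_ng_per_ml", "day", "replicate", "value")
  missing <- setdiff(req, names(tab))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  if (nrow(tab) == 0L) stop("empty input: ", path)
  structure(data.frame(level = tab$level_ng_per_ml, day = tab$day,
                       replicate = tab$replicate, value = tab$value),
            class = c("qc_batch", "data.frame"))
}

fmt2 <- function(x) formatC(x, format = "f", digits = 2)

#' Render a plain-text analysis report
#'
#' Deterministic human-readable report of a pharmacokinetic cohort
#' summary and any validation tables supplied, with numbers rounded to
#' two decimals for display (computation keeps full precision). Sections
#' without content are omitted entirely.
#'
#' @param nca_summary optional [summarize_cohort()] table.
#' @param intraday,interday optional validation tables (after
#'   [acceptance_flags()] if flags are wanted).
#' @param stability optional [stability_rows()] table.
#' @param title report heading.
#' @return Character vector of report lines.
#' @export
render_report <- function(nca_summary = NULL, intraday = NULL,
                          interday = NULL, stability = NULL,
                          title = "Pharmacokinetic and validation report") {
  lines <- c(title, strrep("=", nchar(title)))
  if (!is.null(nca_summary) && nrow(nca_summary)) {
    lines <- c(lines, "", "Pharmacokinetic parameters (mean +/- SD)",
               vapply(seq_len(nrow(nca_summary)), function(i) {
                 r <- nca_summary[i, ]
                 sprintf("  %-10s %-9s %s%s", r$parameter, r$unit,
                         fmt2(r$mean),
                         if (is.na(r$sd)) "" else paste0(" +/- ", fmt2(r$sd)))
               }, character(1)))
  }
  val_section <- function(tab, heading) {
    if (is.null(tab) || !nrow(tab)) return(character(0))
    c("", heading,
      sprintf("  %-8s %-10s %-8s %-7s %-7s %s", "level", "mean", "SD",
              "RSD%", "RE%", if ("pass" %in% names(tab)) "pass" else ""),
      vapply(seq_len(nrow(tab)), function(i) {
        r <- tab[i, ]
        sprintf("  %-8s %-10s %-8s %-7s %-7s %s", fmt2(r$level),
                fmt2(r$measured_mean), fmt2(r$sd), fmt2(r$rsd_pct),
                fmt2(r$re_pct),
                if ("pass" %in% names(tab)) ifelse(r$pass, "yes", "NO") else "")
      }, character(1)))
  }
  lines <- c(lines,
             val_section(intraday, "Intra-day precision and accuracy"),
             val_section(interday, "Inter-day precision and accuracy"))
  if (!is.null(stability) && nrow(stability)) {
    lines <- c(lines, "", "Stability (% remained; stable within +/- 5%)",
               vapply(seq_len(nrow(stability)), function(i) {
                 r <- stability[i, ]
                 sprintf("  %-22s %8s ng/mL  %7s%%  %s", r$condition,
                         fmt2(r$level), fmt2(r$pct_remained),
                         ifelse(r$stable, "stable", "UNSTABLE"))
               }, character(1)))
  }
  lines
}
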
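#' Load the packaged first-in-man trial patient table
#'
#' Per-patient summary of the published 15-patient first-in-man seizure
#' advisory trial: demographics, seizure frequencies at enrollment (patient
#' diary, `sf_pt`, versus iEEG-confirmed, `sf_eeg`, both per month), phase
#' completion flags with failure reasons, seizure counts (clinically
#' correlated seizures, CCS, and CCS plus clinically equivalent seizures),
#' advisory-phase performance (sensitivities, blue NPV, time in high/low
#' states, likelihood ratios with the `"ALL"` sentinel) and notes. Patient
#' 4's blue status is recorded as explicit `unknown` and excluded from blue
#' denominators.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return Object of class `trial_patients` (a validated data frame).
#' @examples
#' tp <- trial_patients()
#' nrow(tp)
#' @export
trial_patients <- function(path = system.file("extdata", "trial_patients.csv",
                                              package = "preictal")) {
  d <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(lr_ccs = "character", lr_ces = "character",
                               blue_enabled = "character"))
  validate_trial_patients(d)
}

.trial_cols <- c("patient", "age", "gender", "zone", "prior_resection",
                 "prior_vns", "aeds", "sf_pt", "sf_eeg", "dc_completed",
                 "dc_reason", "val_completed", "val_reason", "adv_completed",
                 "adv_reason", "blue_enabled", "ccs", "ces_ccs",
                 "sens_ccs_pct", "sens_ces_pct", "npv_pct", "time_high_pct",
                 "time_low_pct", "lr_ccs", "lr_ces", "note")

validate_trial_patients <- function(d) {
  miss <- setdiff(.trial_cols, names(d))
  if (length(miss))
    stop("invalid trial fixture, missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(d) == 0) stop("empty trial table", call. = FALSE)
  pct <- c("sens_ccs_pct", "sens_ces_pct", "npv_pct", "time_high_pct",
           "time_low_pct")
  for (cn in pct) {
    v <- d[[cn]]
    if (any(!is.na(v) & (v < 0 | v > 100)))
      stop("percentage column out of [0, 100]: ", cn, call. = FALSE)
  }
  if (any(d$adv_completed == 1 & d$val_completed != 1, na.rm = TRUE))
    stop("advisory completion implies validation completion", call. = FALSE)
  structure(d, class = c("trial_patients", "data.frame"))
}

#' Write a trial patient table back to CSV
#'
#' Serializes in the fixture's own schema, so that parse-serialize-parse is
#' an identity.
#'
#' @param records A `trial_patients` table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_patients <- function(records, path) {
  stopifnot(inherits(records, "trial_patients"))
  write.csv(as.data.frame(records)[, .trial_cols], path, row.names = FALSE,
            na = "")
  invisible(path)
}

#' Diary-to-EEG seizure-frequency discrepancy ratio
#'
#' The ratio of the patient-reported monthly seizure frequency at enrollment
#' to the monthly frequency confirmed on iEEG, rounded half-up to two
#' decimals. Undefined (NA) when no seizures were captured on EEG.
#'
#' @param sf_pt Patient-reported frequency per month (non-negative).
#' @param sf_eeg iEEG-confirmed frequency per month (non-negative).
#' @return Numeric vector of ratios (NA where `sf_eeg` is 0 or either input
#'   is missing).
#' @examples
#' discrepancy_ratio(4, 14.17)  # 0.28
#' discrepancy_ratio(5, 0.37)   # 13.51
#' discrepancy_ratio(3, 0)      # NA
#' @export
discrepancy_ratio <- function(sf_pt, sf_eeg) {
  if (any(sf_pt < 0, na.rm = TRUE) || any(sf_eeg < 0, na.rm = TRUE))
    stop("seizure frequencies must be non-negative", call. = FALSE)
  out <- ifelse(is.na(sf_pt) | is.na(sf_eeg) | sf_eeg == 0, NA_real_,
                sf_pt / sf_eeg)
  round_half_up(out, 2)
}

#' Summarize the trial patient table
#'
#' Recomputes every derived quantity of the table's average row from the
#' per-patient cells: column means over their non-missing denominators
#' (likelihood-ratio means exclude the `"ALL"` sentinel), phase counts, and
#' the discrepancy-ratio extremes. Each mean is reported with the
#' denominator it was taken over.
#'
#' @param records A [trial_patients()] table.
#' @return Object of class `trial_summary`: a list of `(value, n)` entries
#'   plus count entries.
#' @export
summarize_trial <- function(records) {
  stopifnot(inherits(records, "trial_patients"))
  if (nrow(records) == 0) stop("empty trial table", call. = FALSE)
  d <- records
  mean_of <- function(x, digits) {
    v <- x[!is.na(x)]
    list(value = round_half_up(mean(v), digits), n = length(v))
  }
  lr_num <- function(x) suppressWarnings(as.numeric(x[!is.na(x) & x != "ALL" & x != ""]))
  ratio <- discrepancy_ratio(d$sf_pt, d$sf_eeg)
  n <- nrow(d)
  structure(list(
    n_patients = n,
    age = mean_of(d$age, 1),
    n_resection = sum(d$prior_resection == 1, na.rm = TRUE),
    pct_resection = round_half_up(100 * sum(d$prior_resection == 1, na.rm = TRUE) / n, 0),
    sf_pt = mean_of(d$sf_pt, 2),
    sf_eeg = mean_of(d$sf_eeg, 2),
    ratio_min = min(ratio, na.rm = TRUE),
    ratio_max = max(ratio, na.rm = TRUE),
    ratios = ratio,
    n_dc = sum(d$dc_completed == 1, na.rm = TRUE),
    pct_dc = round_half_up(100 * sum(d$dc_completed == 1, na.rm = TRUE) / n, 0),
    n_val = sum(d$val_completed == 1, na.rm = TRUE),
    pct_val = round_half_up(100 * sum(d$val_completed == 1, na.rm = TRUE) / n, 0),
    n_adv = sum(d$adv_completed == 1, na.rm = TRUE),
    pct_adv = round_half_up(100 * sum(d$adv_completed == 1, na.rm = TRUE) / n, 0),
    ccs = mean_of(d$ccs, 1),
    ces_ccs = mean_of(d$ces_ccs, 1),
    sens_ccs_pct = mean_of(d$sens_ccs_pct, 0),
    sens_ces_pct = mean_of(d$sens_ces_pct, 0),
    npv_pct = mean_of(d$npv_pct, 1),
    time_high_pct = mean_of(d$time_high_pct, 0),
    time_low_pct = mean_of(d$time_low_pct, 0),
    lr_ccs = list(value = round_half_up(mean(lr_num(d$lr_ccs)), 1),
                  n = length(lr_num(d$lr_ccs))),
    lr_ces = list(value = round_half_up(mean(lr_num(d$lr_ces)), 1),
                  n = length(lr_num(d$lr_ces)))
  ), class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf("<trial_summary> %d patients\n", x$n_patients))
  cat(sprintf("  mean age %.1f; prior resection %d (%d%%)\n",
              x$age$value, x$n_resection, x$pct_resection))
  cat(sprintf("  seizure frequency/month: diary %.2f (n=%d) vs iEEG %.2f (n=%d)\n",
              x$sf_pt$value, x$sf_pt$n, x$sf_eeg$value, x$sf_eeg$n))
  cat(sprintf("  discrepancy ratio range %.2f-%.2f\n", x$ratio_min, x$ratio_max))
  cat(sprintf("  phases completed: data collection %d (%d%%), validation %d (%d%%), advisory %d (%d%%)\n",
              x$n_dc, x$pct_dc, x$n_val, x$pct_val, x$n_adv, x$pct_adv))
  cat(sprintf("  mean sensitivity CCS %d%% (n=%d), CES+CCS %d%% (n=%d); blue NPV %.1f%% (n=%d)\n",
              x$sens_ccs_pct$value, x$sens_ccs_pct$n, x$sens_ces_pct$value,
              x$sens_ces_pct$n, x$npv_pct$value, x$npv_pct$n))
  cat(sprintf("  mean time in high %d%% (n=%d), low %d%% (n=%d); LR %.1f / %.1f (n=%d)\n",
              x$time_high_pct$value, x$time_high_pct$n,
              x$time_low_pct$value, x$time_low_pct$n,
              x$lr_ccs$value, x$lr_ces$value, x$lr_ccs$n))
  invisible(x)
}

#' Render a deterministic run report
#'
#' Produces a plain-text report plus a JSON-ready bundle from a trial summary
#' and optional per-patient performance reports; identical inputs give
#' byte-identical output.
#'
#' @param summary A [summarize_trial()] result.
#' @param reports Optional named list of per-run performance bundles (as
#'   produced by [evaluate_timeline()]); entries that are `NULL` are marked
#'   not-evaluable.
#' @param path Optional base path; writes `<path>.txt` and `<path>.json`.
#' @return List with `text` (character lines) and `bundle` (list), invisibly
#'   when `path` is given.
#' @export
render_report <- function(summary, reports = list(), path = NULL) {
  stopifnot(inherits(summary, "trial_summary"))
  txt <- c(
    "== Seizure advisory trial report ==",
    sprintf("patients: %d", summary$n_patients),
    sprintf("mean diary seizure frequency: %.2f/month (n=%d)",
            summary$sf_pt$value, summary$sf_pt$n),
    sprintf("mean iEEG seizure frequency: %.2f/month (n=%d)",
            summary$sf_eeg$value, summary$sf_eeg$n),
    sprintf("diary/EEG discrepancy ratio range: %.2f-%.2f",
            summary$ratio_min, summary$ratio_max),
    sprintf("phase completion: data collection %d/%d, validation %d/%d, advisory %d/%d",
            summary$n_dc, summary$n_patients, summary$n_val,
            summary$n_patients, summary$n_adv, summary$n_patients),
    sprintf("mean red sensitivity (CCS): %d%% (n=%d)",
            summary$sens_ccs_pct$value, summary$sens_ccs_pct$n),
    sprintf("mean blue NPV: %.1f%% (n=%d)", summary$npv_pct$value,
            summary$npv_pct$n),
    sprintf("mean time in high/low advisory: %d%% / %d%%",
            summary$time_high_pct$value, summary$time_low_pct$value)
  )
  if (length(reports)) {
    txt <- c(txt, "", "-- per-run performance --")
    for (nm in names(reports)) {
      r <- reports[[nm]]
      if (is.null(r)) {
        txt <- c(txt, sprintf("%s: not evaluable", nm))
      } else {
        txt <- c(txt, sprintf(
          "%s: sensitivity %.0f%% at %.0f%% red time (improvement %+.2f, p=%.3g), advance: %s",
          nm, 100 * r$red$sensitivity, 100 * r$red$rho_red,
          r$red$improvement, r$red$p_value,
          if (isTRUE(r$verdict$advance)) "yes" else "no"))
      }
    }
  }
  bundle <- list(summary = unclass(summary),
                 reports = lapply(reports, function(r)
                   if (is.null(r)) "not evaluable" else report_to_list(r)))
  if (!is.null(path)) {
    writeLines(txt, paste0(path, ".txt"))
    jsonlite::write_json(bundle, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    return(invisible(list(text = txt, bundle = bundle)))
  }
  list(text = txt, bundle = bundle)
}

report_to_list <- function(r) {
  list(red = unclass(r$red), blue = unclass(r$blue),
       time_fractions = as.list(r$time_fractions),
       likelihood_ratio = list(value = r$likelihood_ratio$value,
                               label = r$likelihood_ratio$label),
       advance = r$verdict$advance)
}
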
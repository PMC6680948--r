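#' Simulation configuration for synthetic chronic iEEG records
#'
#' Builds and validates the configuration object consumed by
#' [simulate_record()] and the individual generators. The generator emulates a
#' chronically implanted multichannel intracranial EEG monitor: a background
#' of 1/f-shaped Gaussian noise per channel, seizure onsets from a
#' refractory-thinned Poisson process, high-amplitude rhythmic ictal bursts, a
#' band-limited pre-ictal power ramp on designated signature channels,
#' antiepileptic-drug (AED) pharmacokinetic levels that can modulate
#' band-limited signal content, and an unreliable patient diary.
#'
#' All times are in seconds from the record origin at 0; intervals are
#' half-open `[start, end)`. A "month" is 30 days throughout.
#'
#' @param duration Record length in seconds.
#' @param sampling_rate Samples per second per channel.
#' @param n_channels Number of recording channels.
#' @param seizure_rate Expected seizure events per 30-day month (the rate of
#'   the thinned process; the underlying Poisson intensity is dead-time
#'   corrected so the realized rate matches).
#' @param refractory Minimum gap between consecutive seizure onsets, seconds.
#' @param preictal_horizon Duration of the pre-ictal signature before each
#'   onset, seconds. Must be shorter than `refractory`.
#' @param effect_size Standardized shift (in baseline standard deviations of
#'   the in-band epoch power, at the reference epoch length
#'   `signature_epoch_ref`) reached by the pre-ictal signature at seizure
#'   onset. 0 plants no signature.
#' @param signature_channels Integer channel indices carrying the signature.
#' @param signature_band Length-2 numeric, Hz passband of the signature.
#' @param signature_epoch_ref Reference epoch length (seconds) used to
#'   standardize `effect_size`; defaults to the device epoch of 13.8 s.
#' @param ictal_duration Seconds of rhythmic ictal burst after each onset.
#' @param ictal_amplitude Burst amplitude in multiples of the background SD.
#' @param aed_halflife AED elimination half-life, seconds.
#' @param aed_dose_interval Dosing interval, seconds.
#' @param aed_coupling List of couplings, each
#'   `list(channel =, band = c(lo, hi), coef =)`: the standardized AED level
#'   multiplies the in-band content of `channel` by `1 + coef * z(aed)`.
#'   Empty list disables the confound.
#' @param diary_report_prob Probability a true seizure is logged in the diary.
#' @param diary_false_rate Spurious diary entries per 30-day month.
#' @param seed Integer seed; identical config + seed gives a bit-identical
#'   record.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(duration = 3600, sampling_rate = 100, n_channels = 4)
#' cfg
#' @export
sim_config <- function(duration,
                       sampling_rate = 400,
                       n_channels = 16,
                       seizure_rate = 4,
                       refractory = 8 * 3600,
                       preictal_horizon = 30 * 60,
                       effect_size = 0,
                       signature_channels = 1L,
                       signature_band = NULL,
                       signature_epoch_ref = 13.8,
                       ictal_duration = 60,
                       ictal_amplitude = 6,
                       aed_halflife = 12 * 3600,
                       aed_dose_interval = 12 * 3600,
                       aed_coupling = list(),
                       diary_report_prob = 1,
                       diary_false_rate = 0,
                       seed = 1L) {
  if (is.null(signature_band)) {
    ny <- sampling_rate / 2
    signature_band <- c(0.4, 0.8) * ny  # upper-half band scaled to Nyquist
  }
  cfg <- structure(list(
    duration = as.numeric(duration),
    sampling_rate = as.numeric(sampling_rate),
    n_channels = as.integer(n_channels),
    seizure_rate = as.numeric(seizure_rate),
    refractory = as.numeric(refractory),
    preictal_horizon = as.numeric(preictal_horizon),
    effect_size = as.numeric(effect_size),
    signature_channels = as.integer(signature_channels),
    signature_band = as.numeric(signature_band),
    signature_epoch_ref = as.numeric(signature_epoch_ref),
    ictal_duration = as.numeric(ictal_duration),
    ictal_amplitude = as.numeric(ictal_amplitude),
    aed_halflife = as.numeric(aed_halflife),
    aed_dose_interval = as.numeric(aed_dose_interval),
    aed_coupling = aed_coupling,
    diary_report_prob = as.numeric(diary_report_prob),
    diary_false_rate = as.numeric(diary_false_rate),
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.finite(cfg$duration) || cfg$duration <= 0)
    stop("duration must be positive", call. = FALSE)
  if (cfg$sampling_rate <= 0) stop("sampling_rate must be positive", call. = FALSE)
  if (cfg$n_channels < 1) stop("n_channels must be >= 1", call. = FALSE)
  if (cfg$seizure_rate < 0) stop("seizure_rate must be >= 0", call. = FALSE)
  if (cfg$refractory < 0) stop("refractory must be >= 0", call. = FALSE)
  if (cfg$preictal_horizon >= cfg$refractory && cfg$refractory > 0)
    stop("preictal_horizon must be shorter than refractory", call. = FALSE)
  if (cfg$diary_report_prob < 0 || cfg$diary_report_prob > 1)
    stop("diary_report_prob must lie in [0, 1]", call. = FALSE)
  if (cfg$diary_false_rate < 0) stop("diary_false_rate must be >= 0", call. = FALSE)
  if (cfg$aed_halflife <= 0) stop("aed_halflife must be positive", call. = FALSE)
  if (cfg$aed_dose_interval <= 0) stop("aed_dose_interval must be positive", call. = FALSE)
  if (length(cfg$signature_band) != 2 || cfg$signature_band[1] >= cfg$signature_band[2])
    stop("signature_band must be c(low, high) with low < high", call. = FALSE)
  if (cfg$signature_band[2] >= cfg$sampling_rate / 2)
    stop("signature_band upper edge must be below Nyquist", call. = FALSE)
  if (any(cfg$signature_channels < 1 | cfg$signature_channels > cfg$n_channels))
    stop("signature_channels out of range", call. = FALSE)
  for (cp in cfg$aed_coupling) {
    if (!all(c("channel", "band", "coef") %in% names(cp)))
      stop("each aed_coupling entry needs channel, band, coef", call. = FALSE)
    if (cp$channel < 1 || cp$channel > cfg$n_channels)
      stop("aed_coupling channel out of range", call. = FALSE)
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d channels @ %g Hz, %.2f days\n",
              x$n_channels, x$sampling_rate, x$duration / 86400))
  cat(sprintf("  seizures: %g/month, refractory %.1f h, horizon %.0f min, effect size %g\n",
              x$seizure_rate, x$refractory / 3600, x$preictal_horizon / 60,
              x$effect_size))
  cat(sprintf("  AED: half-life %.1f h, dosing every %.1f h, %d coupling(s)\n",
              x$aed_halflife / 3600, x$aed_dose_interval / 3600,
              length(x$aed_coupling)))
  cat(sprintf("  diary: report prob %g, false rate %g/month | seed %d\n",
              x$diary_report_prob, x$diary_false_rate, x$seed))
  invisible(x)
}

#' Write or read a simulation configuration as JSON
#'
#' @param cfg A `sim_config` object.
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly; `read_sim_config()`
#'   returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cpl <- raw$aed_coupling
  if (is.null(cpl) || length(cpl) == 0) cpl <- list()
  if (is.data.frame(cpl)) {
    cpl <- lapply(seq_len(nrow(cpl)), function(i)
      list(channel = cpl$channel[i], band = unlist(cpl$band[i]), coef = cpl$coef[i]))
  }
  do.call(sim_config, c(raw[setdiff(names(raw), "aed_coupling")],
                        list(aed_coupling = cpl)))
}

# a 30-day month, used for every per-month rate in the package
seconds_per_month <- function() 30 * 86400
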
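#' Simulate seizure onset times
#'
#' Draws onsets from a homogeneous Poisson process thinned left-to-right to
#' enforce the refractory gap (no two onsets closer than `refractory`). The
#' underlying intensity is dead-time corrected, `lambda* = lambda / (1 -
#' lambda * refractory)`, so the realized event rate matches `seizure_rate`
#' despite thinning.
#'
#' @param config A [sim_config()].
#' @return Numeric vector of strictly increasing onset times in seconds,
#'   consecutive gaps `>= refractory`.
#' @examples
#' cfg <- sim_config(duration = 90 * 86400, sampling_rate = 100,
#'                   n_channels = 1, seizure_rate = 4)
#' simulate_seizure_times(cfg)
#' @export
simulate_seizure_times <- function(config) {
  config <- validate_sim_config(config)
  lambda <- config$seizure_rate / seconds_per_month()  # events per second
  if (lambda == 0) return(numeric(0))
  lt <- lambda * config$refractory
  if (lt >= 1)
    stop(sprintf(
      "infeasible configuration: seizure_rate %g/month cannot honor a %.1f h refractory gap",
      config$seizure_rate, config$refractory / 3600), call. = FALSE)
  lambda_star <- lambda / (1 - lt)
  set.seed(config$seed + 1L)
  n <- rpois(1, lambda_star * config$duration)
  if (n == 0) return(numeric(0))
  cand <- sort(runif(n, 0, config$duration))
  kept <- numeric(n)
  m <- 0L
  last <- -Inf
  for (t in cand) {
    if (t - last >= config$refractory) {
      m <- m + 1L
      kept[m] <- t
      last <- t
    }
  }
  kept[seq_len(m)]
}

#' Simulate antiepileptic-drug levels
#'
#' Superposes first-order elimination curves from periodic unit doses at
#' `0, dose_interval, 2 * dose_interval, ...`: the level at time `t` is
#' `sum over doses at t_i <= t of 2^(-(t - t_i) / halflife)`. The series is
#' strictly positive and, for dosing intervals much shorter than the
#' half-life, approaches the geometric accumulation plateau
#' `1 / (1 - 2^(-interval / halflife))`.
#'
#' @param config A [sim_config()].
#' @param times Times (seconds) at which to evaluate the level; defaults to a
#'   60 s grid over the record.
#' @return Data frame with columns `time_s` and `level` (arbitrary
#'   concentration units, one dose = 1 at ingestion).
#' @examples
#' cfg <- sim_config(duration = 86400, sampling_rate = 100, n_channels = 1,
#'                   aed_halflife = 6 * 3600, aed_dose_interval = 12 * 3600)
#' head(simulate_aed_levels(cfg))
#' @export
simulate_aed_levels <- function(config, times = NULL) {
  config <- validate_sim_config(config)
  if (is.null(times))
    times <- seq(0, config$duration, by = min(60, config$duration))
  H <- config$aed_halflife
  D <- config$aed_dose_interval
  k <- floor(times / D) + 1          # doses taken by time t
  s <- times - (k - 1) * D           # time since most recent dose
  q <- 2^(-D / H)
  # sum_{j=0}^{k-1} 2^(-(s + j*D)/H) in closed form
  level <- 2^(-s / H) * (1 - q^k) / (1 - q)
  data.frame(time_s = times, level = level)
}

#' Simulate an unreliable patient seizure diary
#'
#' Each true event is logged independently with probability
#' `diary_report_prob`; spurious entries arrive as a Poisson process at
#' `diary_false_rate` per month. This reproduces the kind of gross
#' discrepancy observed between patient-reported and EEG-confirmed monthly
#' seizure frequencies in chronic monitoring.
#'
#' @param true_events Numeric vector of true onset times (seconds).
#' @param config A [sim_config()].
#' @return An object of class `diary_log`: data frame with columns `time_s`
#'   and `provenance` (`"true-report"` or `"spurious"`), sorted by time.
#' @export
simulate_diary <- function(true_events, config) {
  config <- validate_sim_config(config)
  set.seed(config$seed + 2L)
  keep <- runif(length(true_events)) < config$diary_report_prob
  reported <- true_events[keep]
  n_false <- rpois(1, config$diary_false_rate * config$duration / seconds_per_month())
  spurious <- sort(runif(n_false, 0, config$duration))
  d <- data.frame(
    time_s = c(reported, spurious),
    provenance = c(rep("true-report", length(reported)),
                   rep("spurious", length(spurious))),
    stringsAsFactors = FALSE
  )
  d <- d[order(d$time_s), , drop = FALSE]
  rownames(d) <- NULL
  structure(d, class = c("diary_log", "data.frame"))
}

#' @export
print.diary_log <- function(x, ...) {
  cat(sprintf("<diary_log> %d entries (%d true reports, %d spurious)\n",
              nrow(x), sum(x$provenance == "true-report"),
              sum(x$provenance == "spurious")))
  if (nrow(x) > 0) print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}
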
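#' Convert a likelihood series to a red/white/blue advisory timeline
#'
#' Maps per-epoch seizure likelihoods to discrete advisory states -- `red`
#' (high likelihood, `>= theta_high`), `blue` (low, `<= theta_low`), `white`
#' (moderate, in between) -- then smooths out dwells shorter than `min_dwell`
#' epochs by merging each short run into its dominant (longer) neighboring
#' run; on a tie the earlier state persists. The result is an ordered,
#' disjoint, exhaustive set of half-open intervals covering the monitored
#' span exactly.
#'
#' @param likelihood Numeric vector of per-epoch likelihoods, on the epoch
#'   grid.
#' @param theta_high,theta_low Advisory thresholds, `theta_high > theta_low`.
#'   A length-2 named vector (as in `sas_algorithm$thresholds`) may be passed
#'   as `theta_high`.
#' @param min_dwell Minimum state dwell, in epochs.
#' @param red_hold Minimum warning duration, in epochs: once the likelihood
#'   exceeds `theta_high`, the red state is held for at least this many
#'   epochs (0 or 1 disables the hold). Red takes precedence over blue.
#' @param epoch_length Epoch length, seconds.
#' @param t0 Time of the first epoch's start, seconds.
#' @return Object of class `advisory_timeline`: data frame with `start_s`,
#'   `end_s`, `state`; attribute `epoch_states` keeps the smoothed per-epoch
#'   state sequence.
#' @export
advisory_from_likelihood <- function(likelihood, theta_high, theta_low = NULL,
                                     min_dwell = 1, red_hold = 0,
                                     epoch_length = 13.8, t0 = 0) {
  if (length(theta_high) == 2 && is.null(theta_low)) {
    theta_low <- unname(theta_high["low"])
    theta_high <- unname(theta_high["high"])
  }
  if (!(theta_high > theta_low))
    stop("theta_high must exceed theta_low", call. = FALSE)
  n <- length(likelihood)
  if (n == 0) return(new_timeline(numeric(0), numeric(0), character(0)))
  red <- likelihood >= theta_high
  if (red_hold > 1) {
    # trailing any-exceedance window: red stays lit for red_hold epochs
    cs <- cumsum(red)
    h <- as.integer(red_hold)
    red <- (cs - c(rep(0L, min(h, n)), cs[seq_len(max(0, n - h))])) > 0
  }
  state <- ifelse(red, "red",
                  ifelse(likelihood <= theta_low, "blue", "white"))
  state <- smooth_dwell(state, min_dwell)
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- c(0, ends[-length(ends)])
  tl <- new_timeline(t0 + starts * epoch_length, t0 + ends * epoch_length,
                     r$values)
  attr(tl, "epoch_states") <- state
  attr(tl, "epoch_length") <- epoch_length
  tl
}

# merge runs shorter than min_dwell into the longer adjacent run
# (tie: the earlier state persists); leftmost short run first
smooth_dwell <- function(state, min_dwell) {
  if (min_dwell <= 1 || length(state) == 0) return(state)
  repeat {
    r <- rle(state)
    short <- which(r$lengths < min_dwell)
    if (length(short) == 0 || length(r$lengths) == 1) break
    i <- short[1]
    if (i == 1) {
      r$values[1] <- r$values[2]
    } else if (i == length(r$values)) {
      r$values[i] <- r$values[i - 1]
    } else if (r$lengths[i - 1] >= r$lengths[i + 1]) {
      r$values[i] <- r$values[i - 1]
    } else {
      r$values[i] <- r$values[i + 1]
    }
    state <- inverse.rle(r)
  }
  state
}

new_timeline <- function(start_s, end_s, state) {
  structure(data.frame(start_s = start_s, end_s = end_s, state = state,
                       stringsAsFactors = FALSE),
            class = c("advisory_timeline", "data.frame"))
}

#' @export
print.advisory_timeline <- function(x, ...) {
  span <- if (nrow(x)) max(x$end_s) - min(x$start_s) else 0
  cat(sprintf("<advisory_timeline> %d interval(s) over %.2f days\n",
              nrow(x), span / 86400))
  for (s in .advisory_states) {
    d <- sum(x$end_s[x$state == s] - x$start_s[x$state == s])
    cat(sprintf("  %-5s %6.1f h (%5.1f%%)\n", s, d / 3600,
                if (span > 0) 100 * d / span else 0))
  }
  invisible(x)
}

#' @export
plot.advisory_timeline <- function(x, ...) {
  cols <- c(red = "firebrick", white = "grey92", blue = "royalblue")
  plot.new()
  plot.window(xlim = range(c(x$start_s, x$end_s)) / 3600, ylim = c(0, 1))
  rect(x$start_s / 3600, 0.25, x$end_s / 3600, 0.75, col = cols[x$state],
       border = NA)
  axis(1)
  title(xlab = "time (h)", main = "Advisory timeline")
  box()
  invisible(x)
}

#' Collapse seizure clusters into single events
#'
#' Events separated by less than `gap` from the previous member of a cluster
#' belong to that cluster, and a cluster counts as a single seizure timed at
#' its first event. A separation of exactly `gap` counts as distinct
#' (clusters require separation *under* the minimum).
#'
#' @param event_times Sorted onset times, seconds.
#' @param gap Minimum separation, seconds (default 8 h).
#' @return Collapsed onset times (first event of each cluster).
#' @examples
#' collapse_clusters(c(0, 2, 20) * 3600) / 3600 # 0, 20
#' @export
collapse_clusters <- function(event_times, gap = 8 * 3600) {
  if (length(event_times) == 0) return(numeric(0))
  if (is.unsorted(event_times)) stop("event_times must be sorted", call. = FALSE)
  keep <- numeric(length(event_times))
  m <- 0L
  last_member <- -Inf
  for (t in event_times) {
    if (t - last_member < gap) {
      last_member <- t          # joins the current cluster
    } else {
      m <- m + 1L
      keep[m] <- t
      last_member <- t
    }
  }
  keep[seq_len(m)]
}

#' Trial screening rules
#'
#' Enrollment requires, over the baseline period: an average of 2 to 12
#' disabling seizures per 30-day month (after cluster collapsing) and no
#' seizure-free interval longer than 45 days (span boundaries included).
#'
#' @param min_monthly,max_monthly Allowed mean monthly seizure counts.
#' @param max_seizure_free_days Longest allowed seizure-free interval, days.
#' @param cluster_gap_hours Minimum separation defining distinct seizures.
#' @return Object of class `screening_rules`.
#' @export
screening_rules <- function(min_monthly = 2, max_monthly = 12,
                            max_seizure_free_days = 45,
                            cluster_gap_hours = 8) {
  stopifnot(min_monthly <= max_monthly, min_monthly > 0,
            max_seizure_free_days > 0, cluster_gap_hours > 0)
  structure(list(min_monthly = min_monthly, max_monthly = max_monthly,
                 max_seizure_free_days = max_seizure_free_days,
                 cluster_gap_hours = cluster_gap_hours),
            class = "screening_rules")
}

#' Screen a candidate's event history for trial eligibility
#'
#' Applies cluster collapsing, then checks the mean monthly rate and the
#' longest seizure-free interval (including the gaps from the span start to
#' the first event and from the last event to the span end).
#'
#' @param events Onset times (diary or confirmed), seconds.
#' @param span Length-2 numeric, observed `c(start, end)` in seconds; must
#'   cover at least the 3-month (90-day) baseline.
#' @param rules A [screening_rules()].
#' @return List: `eligible` (logical), `reasons` (character, failed rules),
#'   `monthly_rate`, `max_gap_days`, `n_collapsed`.
#' @export
eligibility_screen <- function(events, span, rules = screening_rules()) {
  if (length(span) != 2 || span[2] <= span[1])
    stop("span must be c(start, end) with end > start", call. = FALSE)
  span_d <- (span[2] - span[1]) / 86400
  if (span_d < 90)
    stop("span must cover the 3-month baseline period", call. = FALSE)
  ev <- collapse_clusters(sort(events), rules$cluster_gap_hours * 3600)
  ev <- ev[ev >= span[1] & ev < span[2]]
  rate <- length(ev) / (span_d / 30)
  gaps <- diff(c(span[1], ev, span[2])) / 86400
  max_gap <- max(gaps)
  reasons <- character(0)
  if (rate < rules$min_monthly)
    reasons <- c(reasons, sprintf("mean rate %.2f/month below minimum %g",
                                  rate, rules$min_monthly))
  if (rate > rules$max_monthly)
    reasons <- c(reasons, sprintf("mean rate %.2f/month above maximum %g",
                                  rate, rules$max_monthly))
  if (max_gap > rules$max_seizure_free_days)
    reasons <- c(reasons, sprintf("seizure-free interval of %.1f days exceeds %g",
                                  max_gap, rules$max_seizure_free_days))
  list(eligible = length(reasons) == 0, reasons = reasons,
       monthly_rate = rate, max_gap_days = max_gap, n_collapsed = length(ev))
}

#' Identify leading seizures
#'
#' A leading seizure is a confirmed seizure preceded by at least
#' `min_preictal_record` of continuous, seizure-free recording immediately
#' before its onset.
#'
#' @param events Confirmed onset times, seconds.
#' @param coverage Data frame of recorded intervals (`start_s`, `end_s`),
#'   sorted and disjoint.
#' @param min_preictal_record Required preceding interictal recording,
#'   seconds (default 8 h).
#' @return The subset of `events` that are leading.
#' @export
leading_seizures <- function(events, coverage,
                             min_preictal_record = 8 * 3600) {
  if (length(events) == 0) return(numeric(0))
  events <- sort(events)
  ok <- vapply(events, function(ev) {
    w0 <- ev - min_preictal_record
    inside <- any(coverage$start_s <= w0 & coverage$end_s >= ev)
    clean <- !any(events >= w0 & events < ev)
    inside && clean
  }, logical(1))
  events[ok]
}

#' Is data collection complete?
#'
#' The data-collection phase completes once some 30-day sliding window
#' contains at least five leading seizures.
#'
#' @inheritParams leading_seizures
#' @param n_required Leading seizures required within one window.
#' @param window_days Window length, days.
#' @return List: `complete` (logical), `n_leading`, `best_window_count`.
#' @export
data_collection_complete <- function(events, coverage, n_required = 5,
                                     window_days = 30) {
  if (nrow(coverage) == 0) stop("coverage must be non-empty", call. = FALSE)
  lead <- leading_seizures(events, coverage)
  n <- length(lead)
  if (n < n_required)
    return(list(complete = FALSE, n_leading = n,
                best_window_count = n))
  w <- window_days * 86400
  counts <- vapply(seq_len(n), function(i) sum(lead >= lead[i] & lead <= lead[i] + w),
                   integer(1))
  list(complete = max(counts) >= n_required, n_leading = n,
       best_window_count = max(counts))
}

#' Persist and reload an advisory timeline as CSV
#'
#' On-disk format: `start_s,end_s,state`.
#'
#' @param timeline An `advisory_timeline`.
#' @param path File path.
#' @return `write_timeline()` returns `path` invisibly; `read_timeline()`
#'   rebuilds the timeline.
#' @export
write_timeline <- function(timeline, path) {
  stopifnot(inherits(timeline, "advisory_timeline"))
  write.csv(as.data.frame(timeline), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeline
#' @export
read_timeline <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  new_timeline(d$start_s, d$end_s, d$state)
}

#' Lag a likelihood series for causal display
#'
#' The advisory indicator during an epoch can only reflect data already
#' recorded, so the state in effect during epoch `i` is derived from the
#' likelihood of epoch `i - lag` (the most recent completed epoch). The
#' first `lag` epochs repeat the earliest available value.
#'
#' @param likelihood Per-epoch likelihoods.
#' @param lag Non-negative integer lag in epochs.
#' @return The lagged series, same length.
#' @export
lag_likelihood <- function(likelihood, lag = 1L) {
  lag <- as.integer(lag)
  stopifnot(lag >= 0)
  n <- length(likelihood)
  if (lag == 0L || n == 0L) return(likelihood)
  lag <- min(lag, n - 1L)
  c(rep(likelihood[1], lag), likelihood[seq_len(n - lag)])
}
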
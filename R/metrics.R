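#' Fraction of monitored time per advisory state
#'
#' Per-state duration divided by the total monitored span. When the timeline
#' carries its per-epoch state sequence the fractions are computed on epoch
#' counts (exact rationals); either way the three fractions sum to 1 exactly
#' (the moderate fraction is taken as the complement).
#'
#' @param timeline An exhaustive `advisory_timeline`.
#' @return Named numeric vector `c(red =, white =, blue =)`.
#' @export
time_fractions <- function(timeline) {
  stopifnot(inherits(timeline, "advisory_timeline"))
  if (nrow(timeline) == 0) stop("empty timeline", call. = FALSE)
  es <- attr(timeline, "epoch_states")
  if (!is.null(es)) {
    n <- length(es)
    red <- sum(es == "red") / n
    blue <- sum(es == "blue") / n
  } else {
    total <- sum(timeline$end_s - timeline$start_s)
    dur <- function(s) sum(timeline$end_s[timeline$state == s] -
                             timeline$start_s[timeline$state == s])
    red <- dur("red") / total
    blue <- dur("blue") / total
  }
  c(red = red, white = 1 - red - blue, blue = blue)
}

#' Expected sensitivity of a chance predictor
#'
#' Under a warning process statistically independent of seizure onsets, the
#' probability that an onset falls under warning equals the long-run time
#' fraction under warning, so the expected chance sensitivity at
#' time-under-warning `rho` is `rho` itself. An algorithm is only credited
#' with the sensitivity it achieves *above* this benchmark.
#'
#' @param rho Time-under-warning fraction in `[0, 1]`.
#' @return `rho`.
#' @export
chance_sensitivity <- function(rho) {
  stopifnot(all(rho >= 0 & rho <= 1))
  rho
}

#' Sensitivity improvement over the chance predictor
#'
#' @param sensitivity Observed event sensitivity in `[0, 1]`.
#' @param rho Time-under-warning fraction in `[0, 1]`.
#' @return `sensitivity - rho`.
#' @export
improvement_over_chance <- function(sensitivity, rho) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(rho >= 0 & rho <= 1))
  sensitivity - chance_sensitivity(rho)
}

#' One-sided chance test for the high (red) advisory state
#'
#' Conditional on `n_events` onsets and an observed time-under-warning
#' fraction `rho`, a chance predictor captures events as `K ~ Binomial(n,
#' rho)`; the upper-tail p-value `P(K >= n_in_red)` tests whether the
#' observed capture count beats chance.
#'
#' @param n_events Total events in the evaluation window.
#' @param n_in_red Events whose onset fell inside a red interval.
#' @param rho Red time fraction, strictly inside `(0, 1)`.
#' @param alpha Significance level.
#' @return List: `p_value`, `verdict` (`p < alpha`), `n_events`, `n_in_red`,
#'   `rho`. With `n_events = 0` the p-value is `NA` and the result flagged
#'   `undefined`.
#' @export
chance_test_red <- function(n_events, n_in_red, rho, alpha = 0.05) {
  stopifnot(n_in_red <= n_events, n_in_red >= 0)
  if (n_events == 0)
    return(list(p_value = NA_real_, verdict = NA, undefined = TRUE,
                n_events = 0L, n_in_red = 0L, rho = rho))
  if (rho <= 0 || rho >= 1)
    stop("rho must lie strictly inside (0, 1)", call. = FALSE)
  p <- pbinom(n_in_red - 1, n_events, rho, lower.tail = FALSE)
  list(p_value = p, verdict = p < alpha, undefined = FALSE,
       n_events = n_events, n_in_red = n_in_red, rho = rho)
}

#' One-sided chance test for the low (blue) advisory state
#'
#' Tests whether significantly *fewer* seizures occurred under the blue state
#' than chance would place there: lower-tail p-value `P(K <= n_in_blue)` with
#' `K ~ Binomial(n_events, rho_blue)`.
#'
#' @param n_events Total events in the evaluation window.
#' @param n_in_blue Events whose onset fell inside a blue interval.
#' @param rho_blue Blue time fraction, strictly inside `(0, 1)`.
#' @param alpha Significance level.
#' @return As [chance_test_red()], with `n_in_blue` in place of `n_in_red`.
#' @export
chance_test_blue <- function(n_events, n_in_blue, rho_blue, alpha = 0.05) {
  stopifnot(n_in_blue <= n_events, n_in_blue >= 0)
  if (n_events == 0)
    return(list(p_value = NA_real_, verdict = NA, undefined = TRUE,
                n_events = 0L, n_in_blue = 0L, rho_blue = rho_blue))
  if (rho_blue <= 0 || rho_blue >= 1)
    stop("rho_blue must lie strictly inside (0, 1)", call. = FALSE)
  p <- pbinom(n_in_blue, n_events, rho_blue)
  list(p_value = p, verdict = p < alpha, undefined = FALSE,
       n_events = n_events, n_in_blue = n_in_blue, rho_blue = rho_blue)
}

#' Red-state performance of an advisory timeline
#'
#' An event is credited if and only if its onset lies inside a red interval;
#' the advance warning for a credited event is the time from the start of its
#' enclosing red interval to the onset.
#'
#' @param events Onset times within the monitored span, seconds.
#' @param timeline An `advisory_timeline`.
#' @param alpha Significance level of the chance test.
#' @return Object of class `red_performance`: `n_events`, `n_in_red`,
#'   `sensitivity`, `rho_red` (red time fraction),
#'   `advance_warning_min` (per credited event), `improvement`, `p_value`,
#'   `undefined` flag.
#' @export
red_sensitivity <- function(events, timeline, alpha = 0.05) {
  stopifnot(inherits(timeline, "advisory_timeline"))
  if (nrow(timeline) > 0 &&
      (any(events < min(timeline$start_s)) || any(events >= max(timeline$end_s))))
    stop("events outside the monitored span", call. = FALSE)
  fr <- time_fractions(timeline)
  red <- timeline[timeline$state == "red", , drop = FALSE]
  n <- length(events)
  in_red <- logical(n)
  advance <- numeric(0)
  for (i in seq_len(n)) {
    hit <- which(red$start_s <= events[i] & events[i] < red$end_s)
    if (length(hit)) {
      in_red[i] <- TRUE
      advance <- c(advance, (events[i] - red$start_s[hit[1]]) / 60)
    }
  }
  k <- sum(in_red)
  sens <- if (n > 0) k / n else NA_real_
  test <- if (n > 0 && fr["red"] > 0 && fr["red"] < 1)
    chance_test_red(n, k, unname(fr["red"]), alpha)
  else list(p_value = NA_real_, verdict = NA, undefined = TRUE)
  structure(list(
    n_events = n, n_in_red = k, sensitivity = sens,
    rho_red = unname(fr["red"]),
    advance_warning_min = advance,
    improvement = if (n > 0) improvement_over_chance(sens, unname(fr["red"])) else NA_real_,
    p_value = test$p_value, verdict = test$verdict,
    undefined = n == 0, alpha = alpha
  ), class = "red_performance")
}

#' @export
print.red_performance <- function(x, ...) {
  cat("<red_performance>\n")
  if (x$undefined) {
    cat("  no events in window: sensitivity undefined\n")
    return(invisible(x))
  }
  cat(sprintf("  sensitivity %d/%d = %.1f%% at %.1f%% time in red (chance %.1f%%)\n",
              x$n_in_red, x$n_events, 100 * x$sensitivity, 100 * x$rho_red,
              100 * x$rho_red))
  cat(sprintf("  improvement over chance %.3f, p = %.4g\n", x$improvement,
              x$p_value))
  if (length(x$advance_warning_min))
    cat("  advance warnings (min):",
        paste(sprintf("%.1f", x$advance_warning_min), collapse = ", "), "\n")
  invisible(x)
}

#' Blue-state performance of an advisory timeline
#'
#' The blue false negative rate is the fraction of seizures whose onset fell
#' inside a blue (low-likelihood) interval; the episode-based negative
#' predictive value is computed by [blue_npv()].
#'
#' @inheritParams red_sensitivity
#' @return Object of class `blue_performance`: `n_events`, `n_in_blue`,
#'   `fnr`, `rho_blue`, `npv`, `p_value`, `verdict`.
#' @export
blue_fnr <- function(events, timeline, alpha = 0.05) {
  stopifnot(inherits(timeline, "advisory_timeline"))
  fr <- time_fractions(timeline)
  blue <- timeline[timeline$state == "blue", , drop = FALSE]
  n <- length(events)
  k <- sum(vapply(events, function(ev)
    any(blue$start_s <= ev & ev < blue$end_s), logical(1)))
  test <- if (n > 0 && fr["blue"] > 0 && fr["blue"] < 1)
    chance_test_blue(n, k, unname(fr["blue"]), alpha)
  else list(p_value = NA_real_, verdict = NA, undefined = TRUE)
  npv <- if (nrow(blue) > 0) blue_npv(events, timeline) else NA_real_
  structure(list(
    n_events = n, n_in_blue = k,
    fnr = if (n > 0) k / n else NA_real_,
    rho_blue = unname(fr["blue"]), npv = npv,
    p_value = test$p_value, verdict = test$verdict,
    undefined = n == 0, alpha = alpha
  ), class = "blue_performance")
}

#' @export
print.blue_performance <- function(x, ...) {
  cat("<blue_performance>\n")
  if (x$undefined) {
    cat("  no events in window: FNR undefined\n")
    return(invisible(x))
  }
  cat(sprintf("  FNR %d/%d = %.1f%% at %.1f%% time in blue; NPV %s\n",
              x$n_in_blue, x$n_events, 100 * x$fnr, 100 * x$rho_blue,
              if (is.na(x$npv)) "n/a" else sprintf("%.1f%%", 100 * x$npv)))
  cat(sprintf("  p (fewer than chance) = %.4g\n", x$p_value))
  invisible(x)
}

#' Episode-based negative predictive value of the blue state
#'
#' The fraction of blue episodes (maximal blue intervals) containing no
#' seizure onset.
#'
#' @param events Onset times, seconds.
#' @param timeline An `advisory_timeline` with at least one blue episode.
#' @return NPV in `[0, 1]`.
#' @export
blue_npv <- function(events, timeline) {
  blue <- timeline[timeline$state == "blue", , drop = FALSE]
  if (nrow(blue) == 0) {
    warning("no blue episodes: NPV undefined", call. = FALSE)
    return(NA_real_)
  }
  clean <- vapply(seq_len(nrow(blue)), function(i)
    !any(events >= blue$start_s[i] & events < blue$end_s[i]), logical(1))
  mean(clean)
}

#' Likelihood ratio of the high versus moderate advisory states
#'
#' The seizure rate during the high advisory divided by the seizure rate
#' during the moderate advisory. When no events fall in the moderate state
#' the ratio is infinite and reported with the sentinel label `"ALL"` (all
#' events occurred during the high-likelihood advisory).
#'
#' @param events_high,events_moderate Event counts by state.
#' @param time_high,time_moderate Time spent in each state (any common unit),
#'   both strictly positive.
#' @return Object of class `likelihood_ratio`: `value` (numeric, possibly
#'   `Inf`) and `label` (formatted value or `"ALL"`).
#' @examples
#' likelihood_ratio(6, 0.27, 1, 0.66)
#' @export
likelihood_ratio <- function(events_high, time_high, events_moderate,
                             time_moderate) {
  if (time_high <= 0 || time_moderate <= 0)
    stop("state times must be strictly positive", call. = FALSE)
  if (events_high < 0 || events_moderate < 0)
    stop("event counts must be non-negative", call. = FALSE)
  if (events_moderate == 0) {
    return(structure(list(value = Inf, label = "ALL",
                          events_high = events_high, time_high = time_high,
                          events_moderate = 0, time_moderate = time_moderate),
                     class = "likelihood_ratio"))
  }
  v <- (events_high / time_high) / (events_moderate / time_moderate)
  structure(list(value = v, label = sprintf("%.2f", v),
                 events_high = events_high, time_high = time_high,
                 events_moderate = events_moderate,
                 time_moderate = time_moderate),
            class = "likelihood_ratio")
}

#' @export
print.likelihood_ratio <- function(x, ...) {
  cat(sprintf("<likelihood_ratio> %s\n", x$label))
  invisible(x)
}

#' Validation criteria for advancing to the advisory phase
#'
#' The red algorithm passes when its sensitivity exceeds both chance (at the
#' significance level) and the fixed floor; the blue algorithm passes when
#' its false negative rate beats chance. A patient advances when either
#' passes.
#'
#' @param red_floor Minimum red sensitivity (default 0.65).
#' @param alpha Significance level (default 0.05).
#' @return Object of class `validation_criteria`.
#' @export
validation_criteria <- function(red_floor = 0.65, alpha = 0.05) {
  stopifnot(red_floor > 0, red_floor < 1, alpha > 0, alpha < 1)
  structure(list(red_floor = red_floor, alpha = alpha),
            class = "validation_criteria")
}

#' Apply the validation gates to measured performance
#'
#' @param red A `red_performance` (or `NULL` if not evaluable).
#' @param blue A `blue_performance` (or `NULL`).
#' @param criteria A [validation_criteria()].
#' @return Object of class `validation_verdict`: per-color pass/fail with
#'   reasons and the overall `advance` flag (red OR blue).
#' @export
validate_algorithm <- function(red, blue, criteria = validation_criteria()) {
  eval_red <- function() {
    if (is.null(red) || red$undefined)
      return(list(pass = NA, reasons = "not evaluable"))
    reasons <- character(0)
    if (!(red$sensitivity > criteria$red_floor))
      reasons <- c(reasons, sprintf("sensitivity %.2f not above floor %.2f",
                                    red$sensitivity, criteria$red_floor))
    p <- chance_test_red(red$n_events, red$n_in_red,
                         min(max(red$rho_red, 1e-12), 1 - 1e-12),
                         criteria$alpha)
    if (!isTRUE(p$verdict))
      reasons <- c(reasons, sprintf("not above chance (p = %.3g)", p$p_value))
    list(pass = length(reasons) == 0, reasons = reasons)
  }
  eval_blue <- function() {
    if (is.null(blue) || blue$undefined)
      return(list(pass = NA, reasons = "not evaluable"))
    p <- chance_test_blue(blue$n_events, blue$n_in_blue,
                          min(max(blue$rho_blue, 1e-12), 1 - 1e-12),
                          criteria$alpha)
    if (isTRUE(p$verdict)) list(pass = TRUE, reasons = character(0))
    else list(pass = FALSE,
              reasons = sprintf("FNR not below chance (p = %.3g)", p$p_value))
  }
  r <- eval_red()
  b <- eval_blue()
  structure(list(red = r, blue = b,
                 advance = isTRUE(r$pass) || isTRUE(b$pass),
                 criteria = criteria),
            class = "validation_verdict")
}

#' @export
print.validation_verdict <- function(x, ...) {
  show <- function(name, v) {
    status <- if (is.na(v$pass)) "not evaluable" else if (v$pass) "PASS" else "FAIL"
    cat(sprintf("  %-4s %s", name, status))
    if (length(v$reasons) && !isTRUE(v$pass))
      cat(" (", paste(v$reasons, collapse = "; "), ")", sep = "")
    cat("\n")
  }
  cat("<validation_verdict>\n")
  show("red", x$red)
  show("blue", x$blue)
  cat(sprintf("  advance to advisory phase: %s\n",
              if (x$advance) "yes" else "no"))
  invisible(x)
}
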
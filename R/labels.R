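#' Label epochs as pre-ictal, interictal or excluded
#'
#' Training labels contrast a pre-seizure window against interictal time.
#' An epoch is `excluded` when it intersects `[onset, onset +
#' postictal_exclusion)` for any event (ictal and post-ictal time must not
#' contaminate either class); otherwise `preictal` when its midpoint lies in
#' `[onset - horizon, onset)` for some event (overlapping windows merge
#' naturally); otherwise `interictal`. The midpoint rule assigns exactly
#' `floor(horizon / epoch_length)` pre-ictal epochs to an onset aligned with
#' an epoch boundary and never double-labels an epoch.
#'
#' @param epochs Data frame from [segment_epochs()] (columns `start_s`,
#'   `end_s`) or a `feature_matrix`.
#' @param events Onset times, seconds. Events outside the epoch span are
#'   ignored with a warning.
#' @param horizon Pre-ictal window length, seconds (default 30 min).
#' @param postictal_exclusion Seconds excluded from `onset` (default 1 h;
#'   post-ictal feature changes persist for extended durations).
#' @return Character vector (`"preictal"`, `"interictal"`, `"excluded"`), one
#'   per epoch.
#' @export
label_epochs <- function(epochs, events, horizon = 30 * 60,
                         postictal_exclusion = 3600) {
  if (horizon <= 0) stop("horizon must be positive", call. = FALSE)
  if (inherits(epochs, "feature_matrix")) {
    st <- attr(epochs, "epoch_start")
    en <- st + attr(epochs, "grid")$epoch_length
    epochs <- data.frame(start_s = st, end_s = en)
  }
  n <- nrow(epochs)
  labels <- rep("interictal", n)
  if (n == 0 || length(events) == 0) return(labels)
  span_end <- max(epochs$end_s)
  out <- events < epochs$start_s[1] | events >= span_end
  if (any(out)) {
    warning(sprintf("%d event(s) outside the epoch span ignored", sum(out)),
            call. = FALSE)
    events <- events[!out]
  }
  mid <- (epochs$start_s + epochs$end_s) / 2
  pre <- rep(FALSE, n)
  excl <- rep(FALSE, n)
  eps <- 1e-6  # guard against float jitter at epoch/onset boundaries
  for (ev in events) {
    pre <- pre | (mid >= ev - horizon & mid < ev)
    excl <- excl | (epochs$start_s < ev + postictal_exclusion - eps &
                      epochs$end_s > ev + eps)
  }
  labels[pre] <- "preictal"
  labels[excl] <- "excluded"
  labels
}

#' Contiguous block-wise cross-validation folds
#'
#' Splits `n_epochs` consecutive epochs into `k` contiguous, disjoint,
#' exhaustive time blocks whose sizes differ by at most one; the earliest
#' blocks take the remainder. Contiguity prevents temporal leakage between
#' training and test epochs.
#'
#' @param n_epochs Number of epochs (rows), in time order.
#' @param k Number of folds.
#' @return Integer vector of fold ids (1..k), non-decreasing.
#' @examples
#' table(blockwise_folds(103, 10)) # three blocks of 11, seven of 10
#' @export
blockwise_folds <- function(n_epochs, k = 10) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (n_epochs < k)
    stop("n_epochs must be at least k for block-wise folds", call. = FALSE)
  base <- n_epochs %/% k
  rem <- n_epochs %% k
  sizes <- rep(base, k) + c(rep(1L, rem), rep(0L, k - rem))
  rep.int(seq_len(k), sizes)
}

#' Assemble a labeled training dataset
#'
#' Binds a feature matrix to epoch labels, dropping `excluded` and flagged
#' epochs while preserving time order (block-wise folds are computed on the
#' retained rows).
#'
#' @param features A `feature_matrix`.
#' @param labels Labels from [label_epochs()] (same length as epochs).
#' @return Object of class `labeled_dataset`: list with `x` (matrix), `y`
#'   (0 = interictal, 1 = preictal), `epoch_start`, `kept` (row indices into
#'   the original matrix) and `params`.
#' @export
labeled_dataset <- function(features, labels) {
  stopifnot(inherits(features, "feature_matrix"),
            length(labels) == nrow(features))
  keep <- labels != "excluded" & !attr(features, "flagged")
  x <- unclass(features)[keep, , drop = FALSE]
  attr(x, "epoch_start") <- NULL; attr(x, "flagged") <- NULL
  attr(x, "catalog") <- NULL; attr(x, "grid") <- NULL
  structure(list(
    x = x,
    y = as.integer(labels[keep] == "preictal"),
    epoch_start = attr(features, "epoch_start")[keep],
    kept = which(keep),
    catalog = attr(features, "catalog"),
    grid = attr(features, "grid")
  ), class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d epochs (%d preictal, %d interictal), %d features\n",
              length(x$y), sum(x$y == 1), sum(x$y == 0), ncol(x$x)))
  invisible(x)
}
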
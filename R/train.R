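#' Fit the patient classifier on a selected feature subset
#'
#' Fits the regularized linear discriminant on all labeled epochs, restricted
#' to the selected features, and sets the advisory thresholds from
#' training-set likelihood quantiles: `theta_high` at the `1 -
#' red_time_target` quantile (so roughly `red_time_target` of time is spent
#' in the high state) and `theta_low` at the `blue_time_target` quantile.
#' The per-epoch likelihood is the logistic of the discriminant, in `[0, 1]`.
#'
#' @param dataset A [labeled_dataset()] containing both classes.
#' @param selection A `selection_result`.
#' @param lambda Covariance shrinkage weight.
#' @param red_time_target,blue_time_target Target time fractions for the high
#'   and low advisory states used to place the thresholds.
#' @param red_hold_epochs Minimum warning duration in epochs that the
#'   advisory stage will apply; `theta_high` is placed so the *held* red
#'   state covers about `red_time_target` of time (the raw exceedance
#'   quantile is adjusted for the hold).
#' @return Object of class `sas_algorithm`.
#' @export
train_classifier <- function(dataset, selection, lambda = 0.1,
                             red_time_target = 0.25, blue_time_target = 0.45,
                             red_hold_epochs = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(selection, "selection_result"))
  if (length(selection$selected) == 0) stop("empty selection", call. = FALSE)
  y <- dataset$y
  if (!any(y == 1L)) stop("no preictal epochs in dataset", call. = FALSE)
  if (!any(y == 0L)) stop("no interictal epochs in dataset", call. = FALSE)
  ids <- feature_ids(dataset)
  S <- match(selection$selected, ids)
  if (anyNA(S)) stop("selection refers to features absent from dataset", call. = FALSE)
  x <- dataset$x
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  s0 <- colSums(x[y == 0L, , drop = FALSE])
  s1 <- colSums(x[y == 1L, , drop = FALSE])
  cp0 <- crossprod(x[y == 0L, , drop = FALSE])
  cp1 <- crossprod(x[y == 1L, , drop = FALSE])
  fit <- lda_from_stats(n0, n1, s0, s1, cp0, cp1, S, lambda)
  if (fit$floor_applied)
    message("degenerate covariance: regularization floor applied")
  lik <- as.numeric(plogis(x[, S, drop = FALSE] %*% fit$w + fit$b))
  red_hold_epochs <- max(1L, as.integer(red_hold_epochs))
  raw_target <- 1 - (1 - red_time_target)^(1 / red_hold_epochs)
  th_high <- as.numeric(quantile(lik, 1 - raw_target, type = 7))
  th_low <- as.numeric(quantile(lik, blue_time_target, type = 7))
  if (th_high <= th_low) {
    mid <- (th_high + th_low) / 2
    th_high <- mid + 1e-9
    th_low <- mid - 1e-9
  }
  structure(list(
    features = selection$selected,
    w = setNames(as.numeric(fit$w), paste0("f", selection$selected)),
    b = fit$b,
    selection = selection,
    thresholds = c(high = th_high, low = th_low),
    lambda = lambda,
    red_time_target = red_time_target,
    blue_time_target = blue_time_target,
    red_hold_epochs = red_hold_epochs,
    cv_score = selection$score,
    n_train = length(y),
    class_counts = c(interictal = n0, preictal = n1),
    fingerprint = dataset_fingerprint(dataset),
    version = 1L,
    retrain_log = list()
  ), class = "sas_algorithm")
}

dataset_fingerprint <- function(dataset) {
  c(n = length(dataset$y), n_preictal = sum(dataset$y == 1L),
    checksum = round(sum(dataset$x) + sum(dataset$epoch_start), 6))
}

#' Train a patient-specific seizure advisory algorithm
#'
#' The central fitting function: labels the epochs of a feature matrix
#' against confirmed seizure onsets, optionally removes AED-sensitive
#' features, runs forward selection and backward elimination under block-wise
#' cross-validation, and fits the final classifier with advisory thresholds.
#'
#' @param features A `feature_matrix` from [extract_features()].
#' @param events Confirmed seizure onset times, seconds.
#' @param horizon Pre-ictal labeling window, seconds (default 30 min).
#' @param postictal_exclusion Post-onset exclusion, seconds (default 1 h).
#' @param k Number of block-wise cross-validation folds.
#' @param max_size Selected-feature cap (default 16).
#' @param tolerance Score-improvement tolerance for selection steps.
#' @param lambda Covariance shrinkage weight of the discriminant.
#' @param aed_levels Optional AED level series; when supplied, features
#'   failing [aed_stability_screen()] at `aed_threshold` are excluded from
#'   the candidate pool.
#' @param aed_threshold Rank-correlation threshold of the AED screen.
#' @param red_time_target,blue_time_target Threshold placement targets, see
#'   [train_classifier()].
#' @param red_hold Minimum warning duration in seconds (converted to epochs
#'   from the feature matrix's grid); 0 disables the hold.
#' @return A fitted `sas_algorithm`; see [predict.sas_algorithm()],
#'   [advisory_from_likelihood()] and [retrain()].
#' @examples
#' \donttest{
#' cfg <- sim_config(duration = 2 * 86400, sampling_rate = 8, n_channels = 2,
#'                   seizure_rate = 40, refractory = 3 * 3600,
#'                   preictal_horizon = 1200, effect_size = 3,
#'                   signature_band = c(1.5, 3), seed = 7)
#' rec <- simulate_record(cfg)
#' fm <- extract_features(rec, feature_catalog(2, scaled_bands(8)),
#'                        epoch_grid(60))
#' fit <- sas_train(fm, rec$true_events, horizon = 1200, k = 5)
#' summary(fit)
#' }
#' @export
sas_train <- function(features, events, horizon = 30 * 60,
                      postictal_exclusion = 3600, k = 10, max_size = 16,
                      tolerance = 0.002, lambda = 0.1, aed_levels = NULL,
                      aed_threshold = 0.3, red_time_target = 0.25,
                      blue_time_target = 0.45, red_hold = 900) {
  stopifnot(inherits(features, "feature_matrix"))
  candidates <- NULL
  if (!is.null(aed_levels))
    candidates <- aed_stability_screen(features, aed_levels,
                                       aed_threshold)$retained
  labels <- label_epochs(features, events, horizon, postictal_exclusion)
  dataset <- labeled_dataset(features, labels)
  folds <- blockwise_folds(length(dataset$y), k)
  sel <- forward_select(dataset, folds, max_size = max_size,
                        tolerance = tolerance, lambda = lambda,
                        candidates = candidates)
  if (length(sel$selected) == 0) {
    # no feature cleared the improvement tolerance; fit the single best
    # feature anyway so the validation gate (not the selection) decides
    warning("no feature improved on chance beyond tolerance; fitting best single feature",
            call. = FALSE)
    sel <- forward_select(dataset, folds, max_size = 1, tolerance = -Inf,
                          lambda = lambda, candidates = candidates)
  }
  sel <- backward_eliminate(sel, dataset, folds, tolerance = tolerance,
                            lambda = lambda)
  hold_ep <- max(1L, as.integer(round(
    red_hold / attr(features, "grid")$epoch_length)))
  alg <- train_classifier(dataset, sel, lambda = lambda,
                          red_time_target = red_time_target,
                          blue_time_target = blue_time_target,
                          red_hold_epochs = hold_ep)
  alg$settings <- list(horizon = horizon,
                       postictal_exclusion = postictal_exclusion, k = k,
                       max_size = max_size, tolerance = tolerance,
                       lambda = lambda, aed_threshold = aed_threshold,
                       red_hold = red_hold)
  alg
}

#' Predict seizure likelihood from a fitted advisory algorithm
#'
#' @param object A `sas_algorithm`.
#' @param newdata A `feature_matrix` (or any matrix with the selected
#'   feature columns `f<id>`).
#' @param ... Unused.
#' @return Numeric vector of per-epoch likelihoods in `[0, 1]`.
#' @export
predict.sas_algorithm <- function(object, newdata, ...) {
  cols <- paste0("f", object$features)
  miss <- setdiff(cols, colnames(newdata))
  if (length(miss))
    stop("newdata lacks selected features: ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- unclass(newdata)[, cols, drop = FALSE]
  as.numeric(plogis(x %*% object$w + object$b))
}

#' @export
coef.sas_algorithm <- function(object, ...) {
  c(object$w, `(intercept)` = object$b)
}

#' @export
print.sas_algorithm <- function(x, ...) {
  cat(sprintf("<sas_algorithm> v%d: %d feature(s), CV balanced accuracy %.3f\n",
              x$version, length(x$features), x$cv_score))
  cat(sprintf("  thresholds: high %.4f / low %.4f (targets %g%% red, %g%% blue)\n",
              x$thresholds["high"], x$thresholds["low"],
              100 * x$red_time_target, 100 * x$blue_time_target))
  invisible(x)
}

#' @export
summary.sas_algorithm <- function(object, ...) {
  print(object)
  cat(sprintf("  trained on %d epochs (%d preictal / %d interictal)\n",
              object$n_train, object$class_counts["preictal"],
              object$class_counts["interictal"]))
  if (nrow(object$selection$path)) {
    cat("  forward-selection path:\n")
    print(object$selection$path, row.names = FALSE)
  }
  if (nrow(object$selection$elimination_log)) {
    cat("  backward elimination removed:\n")
    print(object$selection$elimination_log, row.names = FALSE)
  }
  if (length(object$retrain_log))
    cat(sprintf("  retrained %d time(s)\n", length(object$retrain_log)))
  invisible(object)
}

#' @export
plot.sas_algorithm <- function(x, ...) {
  p <- x$selection$path
  if (nrow(p) == 0) {
    warning("empty selection path; nothing to plot", call. = FALSE)
    return(invisible(x))
  }
  plot(p$step, p$score, type = "b", xlab = "forward-selection step",
       ylab = "CV balanced accuracy",
       main = "Feature selection path", ...)
  invisible(x)
}

#' Retrain an advisory algorithm on a new data window
#'
#' Algorithm and feature performance drift over months; periodic retraining
#' re-runs selection and classifier fitting on the new window under the
#' stored training settings, increments the version counter and records the
#' selection diff.
#'
#' @param object A fitted `sas_algorithm`.
#' @param features New-window `feature_matrix`.
#' @param events New-window confirmed onsets, seconds.
#' @param ... Overrides passed on to [sas_train()].
#' @return The retrained `sas_algorithm` (version incremented).
#' @export
retrain <- function(object, features, events, ...) UseMethod("retrain")

#' @rdname retrain
#' @export
retrain.sas_algorithm <- function(object, features, events, ...) {
  if (is.null(features) || nrow(features) == 0)
    stop("empty new dataset", call. = FALSE)
  s <- object$settings
  args <- utils::modifyList(
    list(features = features, events = events, horizon = s$horizon,
         postictal_exclusion = s$postictal_exclusion, k = s$k,
         max_size = s$max_size, tolerance = s$tolerance, lambda = s$lambda,
         red_time_target = object$red_time_target,
         blue_time_target = object$blue_time_target,
         red_hold = s$red_hold),
    list(...))
  new <- do.call(sas_train, args)
  new$version <- object$version + 1L
  new$retrain_log <- c(object$retrain_log, list(list(
    from_version = object$version,
    old_selection = object$features,
    new_selection = new$features,
    added = setdiff(new$features, object$features),
    dropped = setdiff(object$features, new$features))))
  new
}
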
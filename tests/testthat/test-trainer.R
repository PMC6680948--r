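test_that("epoch labeling assigns pre-ictal, excluded and interictal windows", {
  ep <- segment_epochs(86400, epoch_grid(13.8))
  expect_true(all(label_epochs(ep, numeric(0), 1800, 3600) == "interictal"))

  # one onset aligned to an epoch boundary: floor(1800/13.8) = 130 pre-ictal
  # epochs before the onset epoch, which itself is excluded
  onset <- 13.8 * 3000
  lab <- label_epochs(ep, onset, horizon = 1800, postictal_exclusion = 3600)
  expect_equal(sum(lab == "preictal"), 130)
  expect_equal(which(lab == "preictal"), 2871:3000)
  expect_equal(lab[3001], "excluded")

  # overlapping pre-ictal windows merge without double labeling
  ev2 <- c(40000, 40000 + 20 * 60)
  lab2 <- label_epochs(ep, ev2, horizon = 1800, postictal_exclusion = 600)
  expect_equal(sort(unique(lab2)), c("excluded", "interictal", "preictal"))
  expect_length(lab2, nrow(ep))

  expect_warning(label_epochs(ep, 2 * 86400, 1800, 3600), "outside")
})

test_that("block-wise folds are contiguous, exhaustive and near-equal", {
  f <- blockwise_folds(100, 10)
  expect_equal(as.integer(table(f)), rep(10L, 10))
  expect_false(is.unsorted(f))
  expect_equal(blockwise_folds(5, 1), rep(1L, 5))
  f2 <- blockwise_folds(103, 10)
  expect_equal(as.integer(table(f2)), c(11L, 11L, 11L, rep(10L, 7)))
  expect_error(blockwise_folds(5, 10), "at least")
  # no temporal leakage: each fold's block is one contiguous run
  for (k in unique(f2)) {
    idx <- which(f2 == k)
    expect_equal(idx, seq(min(idx), max(idx)))
  }
})

test_that("forward selection finds a planted feature first and stops on noise", {
  hits <- vapply(1:20, function(s) {
    ds <- planted_problem(n = 400, d = 288, planted = 97L, effect = 2,
                          seed = s)
    sel <- forward_select(ds, blockwise_folds(400, 10))
    sel$selected[1] == 97L
  }, logical(1))
  expect_gt(mean(hits), 0.9)

  set.seed(50)
  ds0 <- fab_dataset(matrix(rnorm(1000 * 50), 1000, 50),
                     as.integer(seq_len(1000) %% 10 == 0))
  sel0 <- forward_select(ds0, blockwise_folds(1000, 10))
  expect_lt(length(sel0$selected), 6)           # stops early on noise
  # the greedy score is selection-biased upward; on pure noise it still
  # stays well below any usable separation
  expect_lt(sel0$score, 0.65)

  ds <- planted_problem(n = 300, d = 40, planted = 5L, effect = 3, seed = 1)
  sel_cap <- forward_select(ds, blockwise_folds(300, 5), max_size = 2,
                            tolerance = -Inf)
  expect_lte(length(sel_cap$selected), 2)
  expect_lte(length(forward_select(ds, blockwise_folds(300, 5))$selected), 16)
})

test_that("backward elimination prunes redundant and noise features", {
  # duplicated planted feature: one of the pair is eliminated
  ds <- planted_problem(n = 400, d = 30, planted = 3L, effect = 2, seed = 2)
  ds$x[, 9] <- ds$x[, 3]
  folds <- blockwise_folds(400, 10)
  sel <- structure(list(selected = c(3L, 9L), score = 0.5,
                        path = data.frame(),
                        elimination_log = data.frame(feature_id = integer(0),
                                                     score_after = numeric(0))),
                   class = "selection_result")
  pruned <- backward_eliminate(sel, ds, folds)
  expect_length(pruned$selected, 1)
  expect_true(pruned$selected %in% c(3L, 9L))

  # single-feature selections are left untouched
  one <- structure(list(selected = 3L, score = 0.8, path = data.frame(),
                        elimination_log = data.frame()),
                   class = "selection_result")
  expect_identical(backward_eliminate(one, ds, folds)$selected, 3L)

  # planted + pure-noise pair: the noise feature goes
  drops <- vapply(1:10, function(s) {
    dsn <- planted_problem(n = 400, d = 30, planted = 3L, effect = 2,
                           seed = 10 + s)
    seln <- structure(list(selected = c(3L, 17L), score = 0.5,
                           path = data.frame(),
                           elimination_log = data.frame()),
                      class = "selection_result")
    out <- backward_eliminate(seln, dsn, folds)
    identical(out$selected, 3L)
  }, logical(1))
  expect_gt(mean(drops), 0.9)
})

test_that("the classifier separates separable data and fails without a class", {
  ds <- planted_problem(n = 300, d = 10, planted = 2L, effect = 8, seed = 3)
  sel <- forward_select(ds, blockwise_folds(300, 5))
  alg <- train_classifier(ds, sel)
  lik <- plogis(ds$x[, paste0("f", alg$features), drop = FALSE] %*% alg$w + alg$b)
  expect_gt(min(lik[ds$y == 1]), max(lik[ds$y == 0]))
  expect_gt(alg$thresholds["high"], alg$thresholds["low"])

  ds_empty <- fab_dataset(matrix(rnorm(100 * 4), 100, 4), rep(0L, 100))
  expect_error(train_classifier(ds_empty, sel), "preictal")
})

test_that("shuffled labels score at chance", {
  # single-candidate selection removes the max-over-features bias, so the
  # cross-validated score of a shuffled-label fit is a clean chance estimate
  scores <- vapply(1:8, function(s) {
    ds <- planted_problem(n = 400, d = 30, planted = 3L, effect = 2, seed = s)
    set.seed(1000 + s)
    ds$y <- sample(ds$y)
    ds$x <- ds$x[, 3, drop = FALSE]
    colnames(ds$x) <- "f1"
    suppressWarnings(
      forward_select(ds, blockwise_folds(400, 10), max_size = 1,
                     tolerance = -Inf)$score)
  }, 0)
  expect_lt(abs(mean(scores) - 0.5), 0.06)
})

test_that("thresholds track the time-fraction targets", {
  ds <- planted_problem(n = 2000, d = 10, planted = 2L, effect = 1, seed = 6)
  sel <- forward_select(ds, blockwise_folds(2000, 10), tolerance = -Inf,
                        max_size = 1)
  alg <- train_classifier(ds, sel, red_time_target = 0.25,
                          blue_time_target = 0.45, red_hold_epochs = 1L)
  lik <- plogis(ds$x[, paste0("f", alg$features), drop = FALSE] %*% alg$w + alg$b)
  expect_equal(mean(lik >= alg$thresholds["high"]), 0.25, tolerance = 0.02)
  expect_equal(mean(lik <= alg$thresholds["low"]), 0.45, tolerance = 0.02)
})

test_that("retraining on fresh data increments the version and tracks drift", {
  # a feature matrix whose planted column follows the event-derived labels
  fm_with_events <- function(planted, seed) {
    set.seed(seed)
    x <- matrix(rnorm(400 * 30), 400, 30)
    fm <- fab_fm(x, epoch_length = 10)
    ev <- attr(fm, "epoch_start")[seq(20, 400, by = 20)] + 5
    lab <- label_epochs(fm, ev, horizon = 50, postictal_exclusion = 10)
    fm[, planted] <- fm[, planted] + 4 * (lab == "preictal")
    list(fm = fm, ev = ev)
  }
  a <- fm_with_events(3L, 7)
  fit1 <- suppressWarnings(sas_train(a$fm, a$ev, horizon = 50,
                                     postictal_exclusion = 10, k = 5,
                                     red_hold = 0))
  expect_true(3L %in% fit1$features)
  fit_same <- suppressWarnings(retrain(fit1, a$fm, a$ev))
  expect_equal(fit_same$version, 2L)
  expect_identical(sort(fit_same$features), sort(fit1$features))

  # the planted column moves between windows; the new selection follows
  tracks <- vapply(1:10, function(s) {
    d1 <- fm_with_events(3L, 20 + s)
    d2 <- fm_with_events(21L, 40 + s)
    fit <- suppressWarnings(sas_train(d1$fm, d1$ev, horizon = 50,
                                      postictal_exclusion = 10, k = 5,
                                      red_hold = 0))
    fit2 <- suppressWarnings(retrain(fit, d2$fm, d2$ev))
    21L %in% fit2$features
  }, logical(1))
  expect_gt(mean(tracks), 0.8)

  expect_error(retrain(fit1, NULL, a$ev), "empty")
})

test_that("selection is deterministic under a fixed seed", {
  ds <- planted_problem(n = 300, d = 50, planted = 11L, effect = 1, seed = 9)
  folds <- blockwise_folds(300, 10)
  s1 <- forward_select(ds, folds)
  s2 <- forward_select(ds, folds)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$path, s2$path)
})
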
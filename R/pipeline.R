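#' End-to-end run configuration
#'
#' Bundles everything one batch run needs: the simulation configuration, the
#' epoch grid and filter bank, training settings, advisory smoothing,
#' validation criteria and the train/validation split. The `seed` overrides
#' the simulation seed so one integer reproduces the whole run.
#'
#' @param sim A [sim_config()].
#' @param out_dir Output directory for persisted artifacts.
#' @param grid An [epoch_grid()].
#' @param filters Named list of passbands; defaults to [clinical_bands()]
#'   when the sampling rate admits them, else [scaled_bands()].
#' @param horizon,postictal_exclusion,k,max_size,tolerance,lambda,
#'   aed_threshold Training settings, see [sas_train()].
#' @param min_dwell Advisory dwell smoothing, epochs.
#' @param red_hold Minimum warning duration, seconds (see [sas_train()]).
#' @param advisory_lag Causal display lag, in epochs: the advisory state in
#'   effect during an epoch is computed from the likelihood of the epoch
#'   `advisory_lag` steps earlier (the most recent *completed* epoch, default
#'   1). This is the device semantics -- the indicator at seizure onset can
#'   only depend on data recorded before onset.
#' @param criteria A [validation_criteria()].
#' @param train_fraction Leading fraction of epochs used for training; the
#'   remainder is the validation window.
#' @param persist `"full"` (signals as EDF and features as CSV too),
#'   `"light"` (config, events, diary, algorithm, timeline, evaluation) or
#'   `"none"`.
#' @param seed Integer seed recorded in every output.
#' @return Object of class `run_config`.
#' @export
run_config <- function(sim, out_dir = tempfile("sasrun"), grid = epoch_grid(),
                       filters = NULL, horizon = 30 * 60,
                       postictal_exclusion = 3600, k = 10, max_size = 16,
                       tolerance = 0.002, lambda = 0.1, aed_threshold = 0.3,
                       min_dwell = 1, red_hold = 900, advisory_lag = 1L,
                       criteria = validation_criteria(),
                       train_fraction = 2 / 3, persist = "light",
                       seed = sim$seed) {
  stopifnot(inherits(sim, "sim_config"), inherits(grid, "epoch_grid"),
            train_fraction > 0, train_fraction < 1)
  sim$seed <- as.integer(seed)
  if (is.null(filters)) {
    filters <- if (sim$sampling_rate >= 280) clinical_bands()
               else scaled_bands(sim$sampling_rate)
  }
  structure(list(sim = sim, out_dir = out_dir, grid = grid,
                 filters = filters, horizon = horizon,
                 postictal_exclusion = postictal_exclusion, k = k,
                 max_size = max_size, tolerance = tolerance, lambda = lambda,
                 aed_threshold = aed_threshold, min_dwell = min_dwell,
                 red_hold = red_hold, advisory_lag = as.integer(advisory_lag),
                 criteria = criteria, train_fraction = train_fraction,
                 persist = match.arg(persist, c("light", "full", "none")),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Evaluate an advisory timeline against confirmed events
#'
#' Bundles the chance-corrected red performance, blue performance, state time
#' fractions, the high-versus-moderate likelihood ratio and the validation
#' verdict for one evaluation window.
#'
#' @param events Onset times within the monitored span, seconds.
#' @param timeline An `advisory_timeline`.
#' @param criteria A [validation_criteria()].
#' @return Object of class `performance_report`.
#' @export
evaluate_timeline <- function(events, timeline,
                              criteria = validation_criteria()) {
  red <- red_sensitivity(events, timeline, alpha = criteria$alpha)
  blue <- blue_fnr(events, timeline, alpha = criteria$alpha)
  fr <- time_fractions(timeline)
  span <- sum(timeline$end_s - timeline$start_s)
  white <- timeline[timeline$state == "white", , drop = FALSE]
  n_white <- sum(vapply(events, function(ev)
    any(white$start_s <= ev & ev < white$end_s), logical(1)))
  lr <- if (fr["red"] > 0 && fr["white"] > 0)
    likelihood_ratio(red$n_in_red, fr[["red"]] * span, n_white,
                     fr[["white"]] * span)
  else NULL
  verdict <- validate_algorithm(red, blue, criteria)
  structure(list(red = red, blue = blue, time_fractions = fr,
                 likelihood_ratio = lr, verdict = verdict),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  print(x$red)
  print(x$blue)
  if (!is.null(x$likelihood_ratio))
    cat(sprintf("  likelihood ratio (high vs moderate): %s\n",
                x$likelihood_ratio$label))
  print(x$verdict)
  invisible(x)
}

#' Run the full batch pipeline
#'
#' Executes simulate, extract, train, advise and evaluate in sequence on one
#' machine, persisting stage outputs under `config$out_dir` according to
#' `config$persist`. Any stage failure aborts with the stage name and cause.
#' The advisory and evaluation are computed on the held-out validation
#' window (the trailing `1 - train_fraction` of epochs); training never sees
#' it.
#'
#' @param config A [run_config()].
#' @return Object of class `pipeline_result`: list with `record`, `features`,
#'   `algorithm`, `timeline`, `evaluation`, `paths` (persisted artifacts) and
#'   `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  paths <- list()
  persist <- config$persist != "none"
  if (persist) dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  record <- stage("simulate", simulate_record(config$sim))
  if (persist) {
    paths$config <- file.path(config$out_dir, "config.json")
    write_sim_config(config$sim, paths$config)
    paths$events <- file.path(config$out_dir, "events.csv")
    write_events_csv(record$true_events, paths$events)
    paths$diary <- file.path(config$out_dir, "diary.csv")
    write_events_csv(record$diary, paths$diary)
    if (config$persist == "full") {
      paths$edf <- file.path(config$out_dir, "signals.edf")
      write_edf(record, paths$edf)
    }
  }

  catalog <- feature_catalog(config$sim$n_channels, config$filters)
  features <- stage("extract", extract_features(record, catalog, config$grid))
  if (persist && config$persist == "full") {
    paths$features <- file.path(config$out_dir, "features.csv")
    write_feature_matrix(features, paths$features)
  }

  n_ep <- nrow(features)
  m <- floor(n_ep * config$train_fraction)
  if (m < config$k || n_ep - m < 1)
    stop("pipeline stage 'train' failed: record too short for the requested split",
         call. = FALSE)
  t_split <- attr(features, "epoch_start")[m + 1]
  train_fm <- features[seq_len(m), , drop = FALSE]
  train_fm <- restore_fm(train_fm, features, seq_len(m))
  valid_idx <- (m + 1):n_ep
  valid_fm <- restore_fm(features[valid_idx, , drop = FALSE], features, valid_idx)

  train_events <- record$true_events[record$true_events < t_split]
  valid_events <- record$true_events[record$true_events >= t_split]

  algorithm <- stage("train", sas_train(
    train_fm, train_events, horizon = config$horizon,
    postictal_exclusion = config$postictal_exclusion, k = config$k,
    max_size = config$max_size, tolerance = config$tolerance,
    lambda = config$lambda, aed_levels = record$aed_levels,
    aed_threshold = config$aed_threshold, red_hold = config$red_hold))
  if (persist) {
    paths$algorithm <- file.path(config$out_dir, "algorithm.json")
    write_algorithm(algorithm, paths$algorithm, seed = config$seed)
  }

  timeline <- stage("advise", {
    lik <- lag_likelihood(predict(algorithm, valid_fm), config$advisory_lag)
    advisory_from_likelihood(lik, algorithm$thresholds,
                             min_dwell = config$min_dwell,
                             red_hold = algorithm$red_hold_epochs,
                             epoch_length = config$grid$epoch_length,
                             t0 = t_split)
  })
  if (persist) {
    paths$timeline <- file.path(config$out_dir, "advisory.csv")
    write_timeline(timeline, paths$timeline)
  }

  evaluation <- stage("evaluate",
                      evaluate_timeline(valid_events, timeline,
                                        config$criteria))
  if (persist) {
    paths$evaluation <- file.path(config$out_dir, "evaluation.json")
    jsonlite::write_json(c(list(seed = config$seed),
                           report_to_list(evaluation)),
                         paths$evaluation, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }

  structure(list(record = record, features = features,
                 algorithm = algorithm, timeline = timeline,
                 evaluation = evaluation, paths = paths, config = config),
            class = "pipeline_result")
}

# subsetting a feature_matrix with [ drops attributes; restore them
restore_fm <- function(m, parent, idx) {
  structure(m,
            epoch_start = attr(parent, "epoch_start")[idx],
            flagged = attr(parent, "flagged")[idx],
            catalog = attr(parent, "catalog"), grid = attr(parent, "grid"),
            class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$record)
  print(x$algorithm)
  print(x$evaluation)
  invisible(x)
}

#' Serialize a trained algorithm to JSON (and back)
#'
#' @param algorithm A `sas_algorithm`.
#' @param path JSON path.
#' @param seed Optional seed to record alongside.
#' @return `write_algorithm()` returns `path` invisibly; `read_algorithm()`
#'   returns a `sas_algorithm` usable with [predict.sas_algorithm()].
#' @export
write_algorithm <- function(algorithm, path, seed = NULL) {
  stopifnot(inherits(algorithm, "sas_algorithm"))
  obj <- list(seed = seed, version = algorithm$version,
              features = algorithm$features, w = as.list(algorithm$w),
              b = algorithm$b, thresholds = as.list(algorithm$thresholds),
              cv_score = algorithm$cv_score, lambda = algorithm$lambda,
              red_hold_epochs = algorithm$red_hold_epochs,
              red_time_target = algorithm$red_time_target,
              blue_time_target = algorithm$blue_time_target,
              fingerprint = as.list(algorithm$fingerprint))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_algorithm
#' @export
read_algorithm <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(features = as.integer(o$features),
                 w = unlist(o$w), b = o$b,
                 selection = structure(list(selected = as.integer(o$features),
                                            score = o$cv_score,
                                            path = data.frame(),
                                            elimination_log = data.frame()),
                                       class = "selection_result"),
                 thresholds = unlist(o$thresholds),
                 lambda = o$lambda, red_time_target = o$red_time_target,
                 blue_time_target = o$blue_time_target,
                 red_hold_epochs = o$red_hold_epochs,
                 cv_score = o$cv_score, n_train = o$fingerprint$n,
                 class_counts = NULL, fingerprint = unlist(o$fingerprint),
                 version = o$version, retrain_log = list()),
            class = "sas_algorithm")
}

#' Run the pipeline over several seeds
#'
#' Sequential batch runner (optionally forking over seeds) for calibration
#' and recovery studies.
#'
#' @param config A [run_config()]; its seed is replaced by each element of
#'   `seeds`.
#' @param seeds Integer vector of seeds.
#' @param jobs Parallel workers (forked); 1 = sequential.
#' @param summarize Function applied to each `pipeline_result` (default
#'   extracts the evaluation); results are returned as a list.
#' @return List of per-seed summaries, named by seed.
#' @export
run_many_seeds <- function(config, seeds, jobs = 1,
                           summarize = function(r) r$evaluation) {
  one <- function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    cfg$sim$seed <- as.integer(s)
    cfg$persist <- "none"
    summarize(run_pipeline(cfg))
  }
  out <- if (jobs > 1) parallel::mclapply(seeds, one, mc.cores = jobs)
         else lapply(seeds, one)
  names(out) <- as.character(seeds)
  out
}

#' Prospective two-record run: train then advise on a held-out month
#'
#' Mirrors the trial flow: the algorithm is trained on a data-collection
#' record and then evaluated prospectively on an independent monitoring
#' record simulated from the same patient configuration (a disjoint seed
#' stream, `seed + 500000`). Because the advisory process on the held-out
#' record is independent of its seizure process under the null, the chance
#' gates are exactly calibrated here.
#'
#' @param config A [run_config()].
#' @return Object of class `pipeline_result` with the held-out `timeline`
#'   and `evaluation`; `record` is the training record.
#' @export
run_prospective <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sim_val <- config$sim
  sim_val$seed <- config$sim$seed + 500000L
  rec_tr <- simulate_record(config$sim)
  rec_va <- simulate_record(sim_val)
  catalog <- feature_catalog(config$sim$n_channels, config$filters)
  fm_tr <- extract_features(rec_tr, catalog, config$grid)
  fm_va <- extract_features(rec_va, catalog, config$grid)
  algorithm <- sas_train(
    fm_tr, rec_tr$true_events, horizon = config$horizon,
    postictal_exclusion = config$postictal_exclusion, k = config$k,
    max_size = config$max_size, tolerance = config$tolerance,
    lambda = config$lambda, aed_levels = rec_tr$aed_levels,
    aed_threshold = config$aed_threshold, red_hold = config$red_hold)
  lik <- lag_likelihood(predict(algorithm, fm_va), config$advisory_lag)
  timeline <- advisory_from_likelihood(lik, algorithm$thresholds,
                                       min_dwell = config$min_dwell,
                                       red_hold = algorithm$red_hold_epochs,
                                       epoch_length = config$grid$epoch_length)
  ok <- rec_va$true_events < max(timeline$end_s)
  evaluation <- evaluate_timeline(rec_va$true_events[ok], timeline,
                                  config$criteria)
  structure(list(record = rec_tr, validation_record = rec_va,
                 features = fm_tr, algorithm = algorithm,
                 timeline = timeline, evaluation = evaluation,
                 paths = list(), config = config),
            class = "pipeline_result")
}

#' Desk-scale study configuration
#'
#' The fixed configuration used by the package's calibration and
#' signature-recovery experiments: a 30-day, 2-channel record at a strongly
#' reduced 1 Hz sampling rate with 69 s epochs, about 8 seizures per month
#' separated by at least
#' 8 h, a 30-minute pre-ictal horizon, and a 36-feature catalog (2 channels
#' x 6 geometric bands x 3 analyzers). The pre-ictal signature is planted on
#' channel 1 in the fifth band. See the methods vignette for the rationale
#' behind these problem sizes.
#'
#' @param effect_size Standardized pre-ictal shift (0 for null calibration).
#' @param seed Integer seed.
#' @return A [run_config()].
#' @export
desk_config <- function(effect_size = 2, seed = 1) {
  bands <- scaled_bands(1)
  sim <- sim_config(duration = 30 * 86400, sampling_rate = 1, n_channels = 2,
                    seizure_rate = 8, refractory = 8 * 3600,
                    preictal_horizon = 30 * 60, effect_size = effect_size,
                    signature_channels = 1L, signature_band = bands$band5,
                    signature_epoch_ref = 69, seed = seed)
  run_config(sim, grid = epoch_grid(69), filters = bands, persist = "none",
             seed = seed)
}
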
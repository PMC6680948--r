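#' Epoch grid
#'
#' The device processes the record in fixed-length epochs; every feature is a
#' scalar per epoch. The default grid uses non-overlapping 13.8 s epochs
#' aligned to the record start, the display/processing granularity of the
#' advisory device.
#'
#' @param epoch_length Epoch length, seconds.
#' @param hop Start-to-start spacing, seconds; defaults to `epoch_length`
#'   (contiguous, non-overlapping).
#' @return Object of class `epoch_grid`.
#' @export
epoch_grid <- function(epoch_length = 13.8, hop = epoch_length) {
  if (epoch_length <= 0 || hop <= 0)
    stop("epoch_length and hop must be positive", call. = FALSE)
  structure(list(epoch_length = epoch_length, hop = hop), class = "epoch_grid")
}

#' Segment a record into whole epochs
#'
#' Returns the maximal set of whole epochs fitting in the record; a trailing
#' partial epoch is dropped. Epochs are half-open `[start, start +
#' epoch_length)`.
#'
#' @param record An `ieeg_record`, or a duration in seconds.
#' @param grid An [epoch_grid()].
#' @return Data frame with columns `epoch` (1-based index), `start_s`,
#'   `end_s`. Zero rows (with a warning) when the record is shorter than one
#'   epoch.
#' @examples
#' segment_epochs(138, epoch_grid(13.8))
#' @export
segment_epochs <- function(record, grid = epoch_grid()) {
  duration <- if (inherits(record, "ieeg_record"))
    record$config_echo$duration else as.numeric(record)
  n <- if (duration + 1e-9 >= grid$epoch_length)
    floor((duration - grid$epoch_length) / grid$hop + 1e-9) + 1L else 0L
  if (n == 0L) {
    warning("record shorter than one epoch; no epochs produced", call. = FALSE)
    return(data.frame(epoch = integer(0), start_s = numeric(0),
                      end_s = numeric(0)))
  }
  start <- (seq_len(n) - 1) * grid$hop
  data.frame(epoch = seq_len(n), start_s = start,
             end_s = start + grid$epoch_length)
}

#' Canonical clinical frequency bands
#'
#' The six passbands of the default filter layer: delta, theta, alpha, beta,
#' low gamma, high gamma. Suitable for sampling rates of 280 Hz and above
#' (the high-gamma edge must stay below Nyquist).
#'
#' @return Named list of `c(low, high)` Hz pairs.
#' @export
clinical_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), low_gamma = c(30, 70), high_gamma = c(70, 140))
}

#' Geometrically spaced bands for reduced sampling rates
#'
#' Desk-scale runs simulate at strongly reduced sampling rates; this helper
#' splits `(lo_frac, hi_frac)` times Nyquist into `n_bands` geometrically
#' spaced passbands so the filter-layer structure is preserved at any rate.
#'
#' @param sampling_rate Samples per second.
#' @param n_bands Number of bands.
#' @param lo_frac,hi_frac Band-edge fractions of Nyquist.
#' @return Named list of `c(low, high)` Hz pairs.
#' @export
scaled_bands <- function(sampling_rate, n_bands = 6, lo_frac = 0.02,
                         hi_frac = 0.9) {
  ny <- sampling_rate / 2
  edges <- exp(seq(log(lo_frac * ny), log(hi_frac * ny), length.out = n_bands + 1))
  out <- lapply(seq_len(n_bands), function(i) c(edges[i], edges[i + 1]))
  names(out) <- paste0("band", seq_len(n_bands))
  out
}

.analyzer_names <- c("mean_abs_amplitude", "average_power", "line_length")

#' Enumerate the channel-by-filter-by-analyzer feature catalog
#'
#' The master feature set is the full cross-product of channels, band-pass
#' filters and epoch analyzers in channel-major order (then filter, then
#' analyzer), with stable 1-based integer ids. With 16 channels, 6 filters
#' and 3 analyzers this yields the 288-feature master set.
#'
#' @param n_channels Number of channels.
#' @param filters Named list of passbands (`c(low, high)` in Hz), e.g.
#'   [clinical_bands()].
#' @param analyzers Character vector drawn from `"mean_abs_amplitude"`
#'   (mean of the rectified filtered signal), `"average_power"` (mean squared
#'   amplitude) and `"line_length"` (sum of absolute successive differences).
#' @return Object of class `feature_catalog`: data frame with columns
#'   `feature_id`, `channel`, `filter`, `analyzer`, `band_lo`, `band_hi`.
#' @examples
#' nrow(feature_catalog(16)) # 288
#' @export
feature_catalog <- function(n_channels = 16, filters = clinical_bands(),
                            analyzers = .analyzer_names) {
  if (n_channels < 1) stop("n_channels must be >= 1", call. = FALSE)
  if (length(filters) < 1) stop("at least one filter required", call. = FALSE)
  if (length(analyzers) < 1) stop("at least one analyzer required", call. = FALSE)
  if (!all(analyzers %in% .analyzer_names))
    stop("unknown analyzer; choose from: ",
         paste(.analyzer_names, collapse = ", "), call. = FALSE)
  if (is.null(names(filters)) || anyDuplicated(names(filters)))
    stop("filters must be a uniquely named list of passbands", call. = FALSE)
  for (b in filters)
    if (length(b) != 2 || b[1] < 0 || b[1] >= b[2])
      stop("each filter passband must be c(low, high) with 0 <= low < high",
           call. = FALSE)
  grid <- expand.grid(analyzer = analyzers, filter = names(filters),
                      channel = seq_len(n_channels),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("channel", "filter", "analyzer")]
  grid$feature_id <- seq_len(nrow(grid))
  band <- do.call(rbind, filters[grid$filter])
  grid$band_lo <- band[, 1]
  grid$band_hi <- band[, 2]
  rownames(grid) <- NULL
  structure(grid[, c("feature_id", "channel", "filter", "analyzer",
                     "band_lo", "band_hi")],
            filters = filters, analyzers = analyzers,
            n_channels = as.integer(n_channels),
            class = c("feature_catalog", "data.frame"))
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat(sprintf("<feature_catalog> %d features = %d channels x %d filters x %d analyzers\n",
              nrow(x), attr(x, "n_channels"), length(attr(x, "filters")),
              length(attr(x, "analyzers"))))
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Extract the feature matrix from a record
#'
#' For every catalog entry, the channel is band-pass filtered (zero-phase
#' forward-backward Butterworth, order 4, at least 20 dB attenuation one
#' octave outside the passband) and the analyzer is evaluated on each epoch.
#' The first epoch of the record is flagged (filter settling margin), as are
#' epochs whose raw signal is identically zero on every channel.
#'
#' @param record An `ieeg_record`, or a list with elements `signals` and
#'   `sampling_rate`.
#' @param catalog A [feature_catalog()].
#' @param grid An [epoch_grid()]; only non-overlapping grids (`hop ==
#'   epoch_length`) are supported by the fast extraction path.
#' @return Object of class `feature_matrix`: numeric matrix (epochs x
#'   features, columns named `f<id>`) with attributes `epoch_start`
#'   (seconds), `flagged` (logical per epoch), `catalog` and `grid`.
#' @export
extract_features <- function(record, catalog, grid = epoch_grid()) {
  if (inherits(record, "ieeg_record")) {
    signals <- record$signals
    fs <- record$config_echo$sampling_rate
  } else {
    signals <- record$signals
    fs <- record$sampling_rate
  }
  stopifnot(inherits(catalog, "feature_catalog"))
  if (abs(grid$hop - grid$epoch_length) > 1e-12)
    stop("extract_features requires a non-overlapping epoch grid", call. = FALSE)
  if (max(catalog$channel) > length(signals))
    stop("catalog references channels absent from the record", call. = FALSE)
  spe <- round(grid$epoch_length * fs)
  if (abs(spe - grid$epoch_length * fs) > 1e-6)
    spe <- floor(grid$epoch_length * fs)
  if (spe < 2) stop("epoch shorter than two samples at this sampling rate",
                    call. = FALSE)
  n_epochs <- length(signals[[1]]) %/% spe
  if (n_epochs == 0L) {
    warning("record shorter than one epoch", call. = FALSE)
    return(empty_feature_matrix(catalog, grid))
  }
  filters <- attr(catalog, "filters")
  out <- matrix(NA_real_, n_epochs, nrow(catalog),
                dimnames = list(NULL, paste0("f", catalog$feature_id)))
  an_col <- c(mean_abs_amplitude = 1L, average_power = 2L, line_length = 3L)
  for (ch in unique(catalog$channel)) {
    x <- signals[[ch]]
    for (fn in unique(catalog$filter[catalog$channel == ch])) {
      flt <- band_filter_coefs(filters[[fn]], fs)
      stats3 <- cpp_epoch_stats(cpp_filtfilt(flt$b, flt$a, x), spe)
      rows <- which(catalog$channel == ch & catalog$filter == fn)
      for (r in rows)
        out[, paste0("f", catalog$feature_id[r])] <-
          stats3[, an_col[[catalog$analyzer[r]]]]
    }
  }
  flagged <- rep(FALSE, n_epochs)
  flagged[1] <- TRUE
  dead <- rep(TRUE, n_epochs)
  for (ch in seq_along(signals)) {
    rng <- cpp_epoch_stats(signals[[ch]], spe)[, 1]
    dead <- dead & (rng == 0)
  }
  flagged <- flagged | dead
  structure(out,
            epoch_start = (seq_len(n_epochs) - 1) * grid$epoch_length,
            flagged = flagged, catalog = catalog, grid = grid,
            class = c("feature_matrix", "matrix", "array"))
}

empty_feature_matrix <- function(catalog, grid) {
  structure(matrix(numeric(0), 0, nrow(catalog),
                   dimnames = list(NULL, paste0("f", catalog$feature_id))),
            epoch_start = numeric(0), flagged = logical(0),
            catalog = catalog, grid = grid,
            class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d epochs x %d features (epoch %g s, %d flagged)\n",
              nrow(x), ncol(x), attr(x, "grid")$epoch_length,
              sum(attr(x, "flagged"))))
  invisible(x)
}

#' Screen features for antiepileptic-drug sensitivity
#'
#' Features whose epoch series tracks the AED level are unstable for
#' prediction and are excluded before training: any feature with absolute
#' Spearman rank correlation with the AED level (resampled to epoch times)
#' above `threshold` is dropped. A constant AED series disables the screen
#' (all features retained, with a warning).
#'
#' @param matrix A [extract_features()] feature matrix.
#' @param aed_levels Data frame `time_s`/`level` from [simulate_aed_levels()]
#'   or equivalent.
#' @param threshold Absolute rank-correlation threshold for exclusion.
#' @return List with `retained` and `excluded` feature ids and the per-feature
#'   `correlation`.
#' @export
aed_stability_screen <- function(matrix, aed_levels, threshold = 0.3) {
  stopifnot(inherits(matrix, "feature_matrix"))
  ids <- attr(matrix, "catalog")$feature_id
  mids <- attr(matrix, "epoch_start") + attr(matrix, "grid")$epoch_length / 2
  lv <- stats::approx(aed_levels$time_s, aed_levels$level, xout = mids,
                      rule = 2)$y
  if (sd(lv) == 0) {
    warning("constant AED series: stability screen disabled, all features retained",
            call. = FALSE)
    return(list(retained = ids, excluded = integer(0),
                correlation = setNames(rep(NA_real_, length(ids)),
                                       colnames(matrix))))
  }
  rho <- suppressWarnings(
    cor(matrix, lv, method = "spearman", use = "pairwise.complete.obs")[, 1])
  rho[is.na(rho)] <- 0
  excl <- ids[abs(rho) > threshold]
  list(retained = setdiff(ids, excl), excluded = excl, correlation = rho)
}

#' Persist and reload a feature matrix as CSV plus a JSON catalog sidecar
#'
#' @param matrix A `feature_matrix`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.catalog.json`.
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` rebuilds the `feature_matrix`.
#' @export
write_feature_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "feature_matrix"))
  d <- data.frame(epoch_start_s = attr(matrix, "epoch_start"),
                  flagged = attr(matrix, "flagged"))
  d <- cbind(d, as.data.frame(unclass(matrix)[, , drop = FALSE]))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  cat_df <- as.data.frame(attr(matrix, "catalog"))
  jsonlite::write_json(
    list(catalog = cat_df,
         filters = attr(attr(matrix, "catalog"), "filters"),
         analyzers = attr(attr(matrix, "catalog"), "analyzers"),
         n_channels = attr(attr(matrix, "catalog"), "n_channels"),
         epoch_length = attr(matrix, "grid")$epoch_length,
         hop = attr(matrix, "grid")$hop),
    paste0(path, ".catalog.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  d <- read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".catalog.json"),
                              simplifyVector = TRUE)
  filters <- lapply(side$filters, as.numeric)
  cat <- feature_catalog(side$n_channels, filters, side$analyzers)
  m <- as.matrix(d[, -(1:2), drop = FALSE])
  colnames(m) <- paste0("f", cat$feature_id)
  structure(m, epoch_start = d$epoch_start_s, flagged = as.logical(d$flagged),
            catalog = cat,
            grid = epoch_grid(side$epoch_length, side$hop),
            class = c("feature_matrix", "matrix", "array"))
}
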
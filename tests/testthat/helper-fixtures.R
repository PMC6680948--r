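# Builders for in-code fixtures: fabricated feature matrices and labeled
# datasets that skip the signal path, plus a tiny record configuration used
# by pipeline tests.

fab_catalog <- function(n_features) {
  structure(data.frame(feature_id = seq_len(n_features),
                       channel = 1L, filter = "b", analyzer = "average_power",
                       band_lo = 1, band_hi = 2),
            filters = list(b = c(1, 2)), analyzers = "average_power",
            n_channels = 1L,
            class = c("feature_catalog", "data.frame"))
}

fab_fm <- function(x, epoch_length = 10, t0 = 0) {
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  structure(x,
            epoch_start = t0 + (seq_len(nrow(x)) - 1) * epoch_length,
            flagged = rep(FALSE, nrow(x)),
            catalog = fab_catalog(ncol(x)),
            grid = epoch_grid(epoch_length),
            class = c("feature_matrix", "matrix", "array"))
}

fab_dataset <- function(x, y) {
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  structure(list(x = x, y = as.integer(y),
                 epoch_start = (seq_len(nrow(x)) - 1) * 10,
                 kept = seq_len(nrow(x)),
                 catalog = fab_catalog(ncol(x)), grid = epoch_grid(10)),
            class = "labeled_dataset")
}

# labels with preictal epochs spread across all folds, plus a planted
# informative column (standardized shift `effect` on preictal rows)
planted_problem <- function(n = 600, d = 288, planted = 7L, effect = 2,
                            frac_pre = 0.1, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d)
  period <- round(1 / frac_pre)
  y <- as.integer(seq_len(n) %% period == 0)
  x[, planted] <- x[, planted] + effect * y
  fab_dataset(x, y)
}

# small fast simulation used by pipeline tests: 2 days, 2 channels, 2 Hz
tiny_sim <- function(seed = 1, effect_size = 3, seizure_rate = 120) {
  sim_config(duration = 2 * 86400, sampling_rate = 2, n_channels = 2,
             seizure_rate = seizure_rate, refractory = 1.5 * 3600,
             preictal_horizon = 1200, effect_size = effect_size,
             signature_channels = 1L, signature_band = scaled_bands(2)$band5,
             signature_epoch_ref = 60, seed = seed)
}

tiny_run_config <- function(seed = 1, ...) {
  run_config(tiny_sim(seed), grid = epoch_grid(60), filters = scaled_bands(2),
             horizon = 1200, postictal_exclusion = 1800, k = 5,
             red_hold = 300, persist = "none", seed = seed, ...)
}

# an advisory timeline built directly from epoch states
fab_timeline <- function(states, epoch_length = 60, t0 = 0) {
  lik <- ifelse(states == "red", 1, ifelse(states == "blue", 0, 0.5))
  advisory_from_likelihood(lik, theta_high = 0.9, theta_low = 0.1,
                           epoch_length = epoch_length, t0 = t0)
}
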
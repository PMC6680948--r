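test_that("the catalog is the exact channel x filter x analyzer product", {
  cat16 <- feature_catalog(16)
  expect_equal(nrow(cat16), 288)
  expect_equal(cat16$feature_id, 1:288)
  expect_false(anyDuplicated(cat16$feature_id) > 0)
  # channel-major, then filter, then analyzer
  expect_equal(cat16$channel, rep(1:16, each = 18))
  expect_equal(cat16$filter[1:6], rep(c("delta", "theta"), each = 3))

  expect_equal(nrow(feature_catalog(1, list(b = c(1, 2)), "line_length")), 1)
  expect_equal(nrow(feature_catalog(8)), 144)
  # product rule against exhaustive enumeration on small cases
  analyzers <- c("mean_abs_amplitude", "average_power", "line_length")
  for (nc in 1:3) for (nf in 1:3) for (na in 1:3) {
    flt <- setNames(lapply(seq_len(nf), function(i) c(i, i + 1)),
                    paste0("f", seq_len(nf)))
    expect_equal(nrow(feature_catalog(nc, flt, analyzers[seq_len(na)])),
                 nc * nf * na)
  }
  expect_error(feature_catalog(2, list(), "line_length"), "filter")
  expect_error(feature_catalog(2, list(b = c(1, 2)), character(0)), "analyzer")
})

test_that("epoch segmentation keeps whole epochs and drops the remainder", {
  expect_equal(nrow(segment_epochs(138, epoch_grid(13.8))), 10)
  e1 <- segment_epochs(13.8, epoch_grid(13.8))
  expect_equal(nrow(e1), 1)
  expect_equal(e1$end_s, 13.8)
  e2 <- segment_epochs(20, epoch_grid(13.8))
  expect_equal(nrow(e2), 1)  # 6.2 s discarded
  expect_warning(e0 <- segment_epochs(5, epoch_grid(13.8)), "shorter")
  expect_equal(nrow(e0), 0)
})

test_that("analyzers return exact values on null and sinusoidal signals", {
  fs <- 100
  cat1 <- feature_catalog(1, clinical_bands()[1:4])
  zero <- list(signals = list(numeric(fs * 60)), sampling_rate = fs)
  fm <- extract_features(zero, cat1, epoch_grid(10))
  expect_true(all(fm == 0))
  expect_true(all(attr(fm, "flagged")))  # dead record flagged unusable

  # amplitude-A sinusoid inside the alpha band: mean |x| = 2A/pi,
  # mean power = A^2/2, line length = n * 4 A f / fs
  A <- 2; f <- 10.2
  tt <- seq(0, 120 - 1 / fs, by = 1 / fs)
  rec <- list(signals = list(A * sin(2 * pi * f * tt)), sampling_rate = fs)
  fm <- extract_features(rec, feature_catalog(1, clinical_bands()[1:4]),
                         epoch_grid(10))
  cat_df <- attr(fm, "catalog")
  id_maa <- cat_df$feature_id[cat_df$filter == "alpha" &
                              cat_df$analyzer == "mean_abs_amplitude"]
  id_pow <- cat_df$feature_id[cat_df$filter == "alpha" &
                              cat_df$analyzer == "average_power"]
  id_ll <- cat_df$feature_id[cat_df$filter == "alpha" &
                             cat_df$analyzer == "line_length"]
  mid <- 5:8  # interior epochs, away from record edges
  expect_equal(mean(fm[mid, paste0("f", id_maa)]), 2 * A / pi,
               tolerance = 0.03)
  expect_equal(mean(fm[mid, paste0("f", id_pow)]), A^2 / 2, tolerance = 0.05)
  expect_equal(mean(fm[mid, paste0("f", id_ll)]),
               10 * fs * 4 * A * f / fs, tolerance = 0.05)

  # the same tone is rejected by every non-alpha band: out-of-band power
  # at most 1% of in-band power (>= 20 dB attenuation one octave out)
  for (b in c("delta", "theta")) {
    id_out <- cat_df$feature_id[cat_df$filter == b &
                                cat_df$analyzer == "average_power"]
    expect_lt(mean(fm[mid, paste0("f", id_out)]),
              0.01 * mean(fm[mid, paste0("f", id_pow)]))
  }
})

test_that("scaling the signal scales the analyzers with their stated orders", {
  fs <- 50
  set.seed(31)
  x <- as.numeric(cumsum(rnorm(fs * 100))) / 10
  cat1 <- feature_catalog(1, list(b = c(1, 5)))
  f1 <- extract_features(list(signals = list(x), sampling_rate = fs),
                         cat1, epoch_grid(10))
  f3 <- extract_features(list(signals = list(3 * x), sampling_rate = fs),
                         cat1, epoch_grid(10))
  cat_df <- attr(f1, "catalog")
  for (an in c("mean_abs_amplitude", "line_length")) {
    id <- paste0("f", cat_df$feature_id[cat_df$analyzer == an])
    expect_equal(f3[, id], 3 * f1[, id], tolerance = 1e-10)
  }
  id <- paste0("f", cat_df$feature_id[cat_df$analyzer == "average_power"])
  expect_equal(f3[, id], 9 * f1[, id], tolerance = 1e-10)
})

test_that("shifting a stationary record by one epoch permutes feature rows", {
  fs <- 20; L <- 10
  set.seed(7)
  x <- as.numeric(stats::filter(rnorm(fs * 400), 0.9, "recursive"))
  cat1 <- feature_catalog(1, list(b = c(0.5, 4)))
  f_all <- extract_features(list(signals = list(x), sampling_rate = fs),
                            cat1, epoch_grid(L))
  f_shift <- extract_features(list(signals = list(x[-seq_len(fs * L)]),
                                   sampling_rate = fs), cat1, epoch_grid(L))
  # row i of the shifted record is row i+1 of the original (interior rows;
  # record edges differ through the zero-phase filter's padding)
  n <- nrow(f_shift)
  expect_equal(unclass(f_shift)[5:(n - 5), ], unclass(f_all)[6:(n - 4), ],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("the AED stability screen excludes tracking features and calibrates", {
  set.seed(12)
  n <- 500
  aed <- data.frame(time_s = (0:(n - 1)) * 10 + 5,
                    level = abs(sin((0:(n - 1)) / 40)) + 0.2)
  x <- matrix(rnorm(n * 20), n, 20)
  x[, 3] <- aed$level                       # an exact copy of the AED curve
  fm <- fab_fm(x, epoch_length = 10)
  scr <- aed_stability_screen(fm, aed, threshold = 0.5)
  expect_true(3L %in% scr$excluded)
  expect_equal(unname(abs(scr$correlation["f3"])), 1, tolerance = 1e-12)

  # constant series disables the screen
  flat <- data.frame(time_s = aed$time_s, level = rep(1, n))
  expect_warning(scr2 <- aed_stability_screen(fm, flat), "disabled")
  expect_length(scr2$excluded, 0)

  # permutation-calibrated threshold retains ~99% of independent features
  set.seed(13)
  perm <- replicate(300, abs(cor(sample(aed$level), x[, 1],
                                 method = "spearman")))
  thr99 <- quantile(perm, 0.99)
  big <- fab_fm(matrix(rnorm(n * 200), n, 200), epoch_length = 10)
  scr3 <- aed_stability_screen(big, aed, threshold = thr99)
  kept <- length(scr3$retained) / 200
  expect_gt(kept, 0.95)
})

test_that("feature matrices round-trip through CSV with their catalog", {
  cfg <- sim_config(duration = 1200, sampling_rate = 10, n_channels = 2,
                    seizure_rate = 0, seed = 6)
  rec <- simulate_record(cfg)
  fm <- extract_features(rec, feature_catalog(2, scaled_bands(10)),
                         epoch_grid(30))
  path <- tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(unclass(back), unclass(fm), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(attr(back, "epoch_start"), attr(fm, "epoch_start"))
  expect_equal(as.data.frame(attr(back, "catalog")),
               as.data.frame(attr(fm, "catalog")))
  unlink(c(path, paste0(path, ".catalog.json")))
})
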
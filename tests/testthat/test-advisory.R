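test_that("likelihood thresholding produces exhaustive red/white/blue intervals", {
  tl <- advisory_from_likelihood(rep(0.05, 20), 0.8, 0.2, epoch_length = 10)
  expect_equal(nrow(tl), 1)
  expect_equal(tl$state, "blue")
  expect_equal(c(tl$start_s, tl$end_s), c(0, 200))

  lik <- c(rep(0, 7), rep(1, 13))
  tl2 <- advisory_from_likelihood(lik, 0.8, 0.2, epoch_length = 10)
  expect_equal(tl2$state, c("blue", "red"))
  expect_equal(tl2$start_s[2], 70)  # boundary at the step epoch

  expect_equal(nrow(advisory_from_likelihood(numeric(0), 0.8, 0.2)), 0)
  expect_error(advisory_from_likelihood(lik, 0.2, 0.8), "exceed")
})

test_that("dwell smoothing absorbs short states into the dominant neighbor", {
  lik <- rep(c(1, 0), 15)  # alternating single-epoch spikes
  tl <- advisory_from_likelihood(lik, 0.8, 0.2, min_dwell = 3,
                                 epoch_length = 10)
  runs <- rle(attr(tl, "epoch_states"))
  expect_true(all(runs$lengths >= 3))
  # exhaustiveness survives smoothing
  expect_equal(sum(tl$end_s - tl$start_s), 300)
})

test_that("the red hold keeps the warning lit for its minimum duration", {
  lik <- c(rep(0.5, 10), 0.95, rep(0.5, 20))
  tl <- advisory_from_likelihood(lik, 0.9, 0.1, red_hold = 5,
                                 epoch_length = 10)
  red <- tl[tl$state == "red", ]
  expect_equal(nrow(red), 1)
  expect_equal(red$end_s - red$start_s, 50)
  expect_equal(red$start_s, 100)
})

test_that("cluster collapsing follows the eight-hour chaining rule", {
  h <- 3600
  expect_equal(collapse_clusters(c(0, 2, 20) * h), c(0, 20) * h)
  expect_equal(collapse_clusters(42), 42)
  expect_equal(collapse_clusters(c(0, 8) * h), c(0, 8) * h)   # exactly 8 h: distinct
  expect_equal(collapse_clusters(c(0, 7.9) * h), 0)           # under 8 h: one cluster
  # chaining: each member within 8 h of the previous member joins
  expect_equal(collapse_clusters(c(0, 7, 14, 30) * h), c(0, 30) * h)
  # idempotence on random event sets
  set.seed(77)
  for (i in 1:20) {
    ev <- sort(runif(30, 0, 90 * 86400))
    once <- collapse_clusters(ev)
    expect_identical(collapse_clusters(once), once)
  }
})

test_that("eligibility screening applies the 2-12/month and 45-day rules", {
  d <- 86400
  span <- c(0, 90 * d)
  even6 <- seq(7.5, 82.5, by = 15) * d
  v <- eligibility_screen(even6, span)
  expect_true(v$eligible)
  expect_equal(v$monthly_rate, 2)

  v3 <- eligibility_screen(c(20, 45, 70) * d, span)
  expect_false(v3$eligible)
  expect_match(v3$reasons, "below minimum", all = FALSE)

  gap <- eligibility_screen(c(seq(1, 39, 2), 89) * d, span)
  expect_false(gap$eligible)
  expect_match(gap$reasons, "seizure-free", all = FALSE)

  # clusters count once: 30 tight triples are 30 seizures, not 90
  trip <- sort(c(seq(1, 88, 3), seq(1, 88, 3) + 0.05, seq(1, 88, 3) + 0.1)) * d
  vt <- eligibility_screen(trip, span)
  expect_equal(vt$n_collapsed, 30)

  expect_error(eligibility_screen(even6, c(0, 30 * d)), "baseline")
})

test_that("leading seizures require eight clean recorded hours", {
  h <- 3600
  cov <- data.frame(start_s = 0, end_s = 100 * h)
  expect_equal(leading_seizures(c(30, 32) * h, cov), 30 * h)
  expect_equal(leading_seizures(24 * h, cov), 24 * h)
  cov_gap <- data.frame(start_s = c(0, 50 * h), end_s = c(40 * h, 100 * h))
  expect_length(leading_seizures(56 * h, cov_gap), 0)  # 6 h after a gap
  expect_equal(leading_seizures(70 * h, cov_gap), 70 * h)
})

test_that("data collection completes on five leading seizures in one month", {
  d <- 86400
  cov <- data.frame(start_s = 0, end_s = 200 * d)
  five <- c(2, 6, 10, 14, 18) * d
  expect_true(data_collection_complete(five, cov)$complete)
  spread <- seq(2, 182, by = 7.6) * d  # ~4 per month for 6 months
  expect_false(data_collection_complete(spread, cov)$complete)
  expect_false(data_collection_complete(numeric(0), cov)$complete)
  expect_error(data_collection_complete(five, cov[0, ]), "coverage")
})

test_that("timelines persist losslessly as CSV", {
  set.seed(5)
  tl <- advisory_from_likelihood(runif(50), 0.7, 0.3, epoch_length = 13.8)
  path <- tempfile(fileext = ".csv")
  write_timeline(tl, path)
  back <- read_timeline(path)
  for (cn in c("start_s", "end_s", "state"))
    expect_equal(back[[cn]], tl[[cn]])
  unlink(path)
})
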
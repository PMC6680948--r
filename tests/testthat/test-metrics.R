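test_that("state time fractions are exact and exhaustive", {
  all_red <- fab_timeline(rep("red", 10))
  expect_equal(time_fractions(all_red), c(red = 1, white = 0, blue = 0))

  # 14 days with 3.5 days of red advisories: red fraction exactly 1/4
  d14 <- rep("white", 14 * 24)
  d14[c(1:24, 50:73, 100:123, 140:151)] <- "red"   # 84 h = 3.5 days
  tl <- fab_timeline(d14, epoch_length = 3600)
  fr <- time_fractions(tl)
  expect_equal(unname(fr["red"]), 0.25)
  expect_equal(sum(fr), 1, tolerance = 1e-12)

  set.seed(3)
  rnd <- fab_timeline(sample(c("red", "white", "blue"), 997, replace = TRUE))
  expect_equal(sum(time_fractions(rnd)), 1, tolerance = 1e-12)
  expect_error(time_fractions(fab_timeline(character(0))), "empty")
})

test_that("red performance credits onsets inside red and measures warnings", {
  st <- rep("white", 1000)
  st[101:110] <- "red"
  tl <- fab_timeline(st, epoch_length = 60)
  # event onsets inside the red interval [6000, 6600)
  r <- red_sensitivity(c(6030, 6300, 6590), tl)
  expect_equal(r$sensitivity, 1)

  # 6 of 7 events in red
  st2 <- rep("white", 1000)
  for (s in c(1, 101, 201, 301, 401, 501)) st2[s:(s + 9)] <- "red"
  tl2 <- fab_timeline(st2, epoch_length = 60)
  ev7 <- c((c(1, 101, 201, 301, 401, 501) - 1) * 60 + 30, 50000)
  r2 <- red_sensitivity(ev7, tl2)
  expect_equal(r2$n_in_red, 6)
  expect_equal(round(100 * r2$sensitivity), 86)

  # advance warnings are onset minus red-interval start, in minutes
  st3 <- rep("white", 3000)
  starts <- c(100, 1000, 2000)
  for (s in starts) st3[s:(s + 59)] <- "red"
  tl3 <- fab_timeline(st3, epoch_length = 60)
  onsets <- (starts - 1) * 60 + c(14.9, 6.3, 29.7) * 60
  r3 <- red_sensitivity(onsets, tl3)
  expect_equal(r3$advance_warning_min, c(14.9, 6.3, 29.7))

  r0 <- red_sensitivity(numeric(0), tl3)
  expect_true(r0$undefined)
})

test_that("chance sensitivity equals the time fraction under warning", {
  expect_identical(chance_sensitivity(0), 0)
  expect_identical(chance_sensitivity(1), 1)
  # Monte Carlo: warnings independent of events capture rho of onsets
  set.seed(19)
  caps <- replicate(300, {
    off_d <- rexp(200, 1 / 2000)      # alternating renewal process of
    on_d <- rexp(200, 1 / 666)        # warnings: ~25% of time under warning
    ends <- cumsum(off_d + on_d)
    on_start <- ends - on_d
    ev <- runif(30, 0, ends[200])
    mean(vapply(ev, function(t) any(on_start <= t & t < ends), logical(1)))
  })
  expect_equal(mean(caps), 0.25, tolerance = 0.02)

  expect_equal(improvement_over_chance(0.86, 0.27), 0.59)
  expect_equal(improvement_over_chance(0.4, 0.4), 0)
})

test_that("binomial chance tests match their closed forms", {
  t1 <- chance_test_red(3, 3, 0.31)
  expect_equal(t1$p_value, 0.31^3)
  expect_true(t1$verdict)
  expect_equal(chance_test_red(5, 0, 0.4)$p_value, 1)
  expect_true(chance_test_red(0, 0, 0.5)$undefined)

  t2 <- chance_test_blue(3, 0, 0.56)
  expect_equal(t2$p_value, (1 - 0.56)^3)
  expect_false(t2$verdict)    # 0.085 is not below 0.05
  expect_equal(chance_test_blue(4, 4, 0.3)$p_value, 1)
})

test_that("blue NPV counts clean episodes", {
  st <- rep("white", 500)
  for (s in seq(1, 491, by = 10)) st[s:(s + 4)] <- "blue"   # 50 episodes
  tl <- fab_timeline(st, epoch_length = 60)
  expect_equal(blue_npv(numeric(0), tl), 1)
  expect_equal(blue_npv(90, tl), 0.98)          # one episode contaminated
  every <- (seq(1, 491, by = 10) - 1) * 60 + 30
  expect_equal(blue_npv(every, tl), 0)
  expect_warning(npv <- blue_npv(1, fab_timeline(rep("red", 5))), "undefined")
  expect_true(is.na(npv))
})

test_that("the likelihood ratio reproduces the rate-ratio definition", {
  lr <- likelihood_ratio(6, 0.27, 1, 0.66)
  expect_equal(lr$value, (6 / 0.27) / (1 / 0.66), tolerance = 1e-12)
  expect_equal(round(lr$value, 2), 14.67)
  expect_identical(likelihood_ratio(3, 0.2, 0, 0.5)$label, "ALL")
  expect_identical(likelihood_ratio(3, 0.2, 0, 0.5)$value, Inf)
  expect_equal(likelihood_ratio(2, 0.5, 2, 0.5)$value, 1)
  expect_error(likelihood_ratio(2, 0, 1, 0.5), "positive")
})

test_that("validation gates combine the floor and the chance tests", {
  mk_red <- function(n, k, rho) {
    structure(list(n_events = n, n_in_red = k, sensitivity = k / n,
                   rho_red = rho, advance_warning_min = numeric(0),
                   improvement = k / n - rho,
                   p_value = chance_test_red(n, k, rho)$p_value,
                   verdict = NA, undefined = FALSE, alpha = 0.05),
              class = "red_performance")
  }
  mk_blue <- function(n, k, rho) {
    structure(list(n_events = n, n_in_blue = k, fnr = k / n, rho_blue = rho,
                   npv = NA_real_,
                   p_value = chance_test_blue(n, k, rho)$p_value,
                   verdict = NA, undefined = FALSE, alpha = 0.05),
              class = "blue_performance")
  }
  v <- validate_algorithm(mk_red(7, 6, 0.27), NULL)
  expect_true(v$red$pass)
  expect_true(v$advance)

  v2 <- validate_algorithm(mk_red(10, 6, 0.27), NULL)  # 0.60 below floor
  expect_false(v2$red$pass)

  v3 <- validate_algorithm(mk_red(10, 6, 0.27), mk_blue(8, 0, 0.45))
  expect_false(v3$red$pass)
  expect_true(v3$blue$pass)
  expect_true(v3$advance)   # blue alone advances the patient

  v4 <- validate_algorithm(NULL, NULL)
  expect_true(is.na(v4$red$pass))
  expect_false(v4$advance)
})
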
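test_that("Weibull survival has the closed-form values and shape", {
  expect_equal(weibull_survival(0, 5, 14), 1)
  # t = b forces exponent -1 regardless of shape
  for (a in c(0.5, 2, 5, 50))
    expect_equal(weibull_survival(14, a, 14), exp(-1))
  expect_equal(weibull_survival(7, 2, 14), exp(-0.25))
  s <- weibull_survival(0:50, 4, 20)
  expect_true(all(diff(s) < 0))
  expect_true(all(s >= 0 & s <= 1))
  expect_error(weibull_survival(1, -1, 10), "positive")
  expect_error(weibull_survival(1, 2, 0), "positive")
  expect_error(weibull_survival(-1, 2, 10), "non-negative")
})

test_that("generate_curve realises the Weibull model day by day", {
  p <- simulator_params(10, a = 50, b = 14, seed = 1)
  cu <- generate_curve(p)
  # near-deterministic deaths around day 14 for a sharp shape
  expect_true(all(cu$live_counts[1:13] == 10))
  expect_lte(length(cu$live_counts), 16)
  expect_equal(cu$live_counts[length(cu$live_counts)], 0L)

  p12 <- simulator_params(12, a = 5, b = 14, seed = 42)
  cu12 <- generate_curve(p12)
  expect_identical(cu12$live_counts[1L], 12L)
  expect_true(all(diff(cu12$live_counts) <= 0L))
  # seeded determinism
  expect_identical(generate_curve(p12), cu12)

  det <- generate_curve(simulator_params(10, a = 5, b = 14), "deterministic")
  expect_identical(det$live_counts,
                   cummin(as.integer(round(
                     10 * weibull_survival(det$days, 5, 14)))))
})

test_that("simulator parameter validation flags out-of-range designs", {
  expect_error(simulator_params(10, a = 0, b = 14), "positive")
  expect_error(simulator_params(10, a = 5, b = 14, max_days = 5),
               "max_days")
  expect_warning(simulator_params(25, a = 5, b = 14), "design range")
  expect_warning(simulator_params(12, a = 5, b = 80, max_days = 200),
                 "design range")
})

test_that("capture gaps hold the last captured count and then catch up", {
  cu <- curve_of(10, 9, 8, 7, 6, 5, 4, 3, 2, 1, 0)
  # fixed phase so that days 2 and 3 are gap days
  gs <- gap_spec(gap_len = 2, period = 7, phase = 2, prob = 1)
  out <- apply_capture_gaps(cu, gs)
  expect_equal(out$live_counts[3:4], c(9L, 9L))   # held at day-1 value
  expect_equal(out$live_counts[5], 6L)            # true day-4 count restored
  # total deaths unchanged and monotone
  expect_equal(out$live_counts[length(out$live_counts)], 0L)
  expect_true(all(diff(out$live_counts) <= 0L))

  # prob = 0 leaves the curve untouched
  set.seed(1)
  expect_identical(apply_capture_gaps(cu, gap_spec(prob = 0))$live_counts,
                   cu$live_counts)
  expect_error(apply_capture_gaps(curve_of(3, 0), gap_spec(gap_len = 2)),
               "shorter")
})

test_that("gaps never increase a count, for any phase", {
  set.seed(7)
  for (i in 1:20) {
    p <- suppressWarnings(simulator_params(sample(10:15, 1),
                                           a = runif(1, 3, 10),
                                           b = runif(1, 10, 25)))
    cu <- generate_curve(p)
    out <- apply_capture_gaps(cu, gap_spec(prob = 1))
    expect_true(all(diff(out$live_counts) <= 0L))
    expect_equal(out$live_counts[length(out$live_counts)], 0L)
    expect_identical(out$initial_count, cu$initial_count)
  }
})

test_that("trajectories conserve the curve and freeze dead worms", {
  cu <- curve_of(3, 3, 0)
  tr <- sample_trajectories(cu, tiny_arena(), seed = 3)
  # all three move day 0 -> 1, none moves day 1 -> 2
  expect_false(any(tr$positions[, , 1] == tr$positions[, , 2]))
  expect_identical(tr$positions[, , 2], tr$positions[, , 3])

  pl <- make_plate(11)
  tr <- pl$trajectories
  expect_equal(colSums(tr$alive_mask), pl$curve$live_counts)
  n_days <- dim(tr$positions)[3]
  for (w in seq_len(nrow(tr$alive_mask))) {
    dd <- tr$death_day[w]
    if (!is.na(dd) && dd + 1L < n_days)
      for (d in (dd + 1L):(n_days - 1L))
        expect_identical(tr$positions[w, , d + 1L], tr$positions[w, , dd + 1L])
  }
  # reproducibility
  tr2 <- sample_trajectories(pl$curve, tiny_arena(), seed = 5)
  tr3 <- sample_trajectories(pl$curve, tiny_arena(), seed = 5)
  expect_identical(tr2, tr3)
})

test_that("empirical survival over many plates matches the Weibull law", {
  # 500 plates, n = 15, a = 5, b = 20: the empirical per-day survival
  # fraction must converge to exp(-(t/b)^a) within binomial error
  n_plates <- 500L; n <- 15L; a <- 5; b <- 20
  horizon <- 35L
  tot <- numeric(horizon + 1L)
  set.seed(123)
  for (i in seq_len(n_plates)) {
    cu <- generate_curve(simulator_params(n, a, b, max_days = 60L))
    counts <- c(cu$live_counts, rep(0L, horizon + 1L - length(cu$live_counts)))
    tot <- tot + counts[seq_len(horizon + 1L)]
  }
  emp <- tot / (n_plates * n)
  expected <- weibull_survival(0:horizon, a, b)
  # binomial MC tolerance: 4 standard errors per day
  se <- sqrt(expected * (1 - expected) / (n_plates * n))
  expect_true(all(abs(emp - expected) <= 4 * se + 1e-9))
})
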
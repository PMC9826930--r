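test_that("event reconstruction from count curves conserves worms", {
  ev <- curve_to_events(c(10, 8, 8, 5, 0))
  expect_equal(ev$day, c(1L, 3L, 4L))
  expect_equal(ev$deaths, c(2L, 3L, 5L))
  expect_equal(sum(ev$deaths) + attr(ev, "censored"), attr(ev, "initial"))

  none <- curve_to_events(c(7, 7, 7))
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "censored"), 7)
  expect_error(curve_to_events(c(5, 6)), "monotonicity|non-increasing")

  set.seed(4)
  for (i in 1:10) {
    cc <- random_curve()
    ev <- curve_to_events(cc)
    expect_equal(sum(ev$deaths) + attr(ev, "censored"), cc[1])
  }
})

test_that("log-rank handles degenerate and hand-computed cases", {
  # identical curves: O - E = 0 at every event time
  lr <- logrank_test(c(10, 7, 3, 0), c(10, 7, 3, 0))
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)

  # hand-expanded hypergeometric sums for [4,0] vs [4,4,4,4,0]
  got <- logrank_test(c(4, 0), c(4, 4, 4, 4, 0))
  want <- brute_force_logrank(c(4, 0), c(4, 4, 4, 4, 0))
  expect_equal(got$statistic, want$stat, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)
  # day-1 table: 4 of 8 at risk die, all in group 1
  expect_equal(got$table$e1[1], 4 * 4 / 8)

  # label symmetry
  sw <- logrank_test(c(4, 4, 4, 4, 0), c(4, 0))
  expect_equal(sw$statistic, got$statistic, tolerance = 1e-12)

  expect_error(logrank_test(c(5, 5), c(3, 3)), "no death")
})

test_that("log-rank agrees with survival::survdiff on random curve pairs", {
  skip_if_not_installed("survival")
  set.seed(99)
  n_checked <- 0L
  while (n_checked < 50L) {
    ca <- random_curve(); cb <- random_curve()
    df <- rbind(curve_to_surv_df(ca, 1L), curve_to_surv_df(cb, 2L))
    # survdiff needs at least one event and both groups
    if (sum(df$status) == 0L) next
    sd_fit <- survival::survdiff(survival::Surv(time, status) ~ group,
                                 data = df)
    got <- logrank_test(ca, cb)
    expect_equal(got$statistic, unname(sd_fit$chisq), tolerance = 1e-7)
    p_ref <- pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE)
    if (p_ref > 1e-12)
      expect_equal(got$p_value, p_ref, tolerance = 1e-7)
    n_checked <- n_checked + 1L
  }
})

test_that("the halting verdict follows the band geometry", {
  mkband <- function(lower, upper, obs, alpha = 0.05) {
    k <- length(obs) - 1L
    structure(list(days = k + seq_along(lower), mean_curve = (lower + upper) / 2,
                   std_curve = (upper - lower) / 4, ci_lower = lower,
                   ci_upper = upper, obs_prefix = obs,
                   total_initial = obs[1L], alpha = alpha, n_plates = 4L),
              class = "condition_band")
  }
  # zero-uncertainty band: identical bounds, halt with p = 1
  dec <- halt_decision(mkband(c(30, 15, 0), c(30, 15, 0), c(50, 45, 40)))
  expect_true(dec$halt)
  expect_equal(dec$p_value, 1)

  # maximally separated bounds: lower extinct immediately, upper constant
  wide <- halt_decision(mkband(c(0, 0, 0, 0, 0, 0), rep(40, 6),
                               c(50, 45, 40)))
  expect_false(wide$halt)
  expect_lt(wide$p_value, 0.05)

  # monotone in alpha: halting at 5% implies halting at any smaller alpha
  mid <- mkband(c(35, 20, 8, 0), c(40, 28, 14, 2), c(50, 45, 42))
  d05 <- halt_decision(mid, alpha = 0.05)
  if (d05$halt) expect_true(halt_decision(mid, alpha = 0.01)$halt)

  # fractional bounds are rounded half-up before testing
  frac <- mkband(c(29.6, 14.2, 0.4), c(30.4, 15.49, 0.2), c(50, 45, 40))
  dec2 <- halt_decision(frac)
  expect_equal(dec2$lower_curve, c(50L, 45L, 40L, 30L, 14L, 0L))
  expect_equal(dec2$upper_curve, c(50L, 45L, 40L, 30L, 15L, 0L))
})

test_that("the halting scan starts at the common first drop and traces p", {
  pl <- lapply(c(61, 62, 63), function(s) make_plate(s))
  orc <- oracle_predictor(lapply(pl, `[[`, "curve"), max_days = 40)
  hr <- find_halt_day(orc, pl, noise = noise_spec(10, 1, seed = 3))
  start <- max(vapply(pl, function(p) first_drop_day(p$curve), integer(1)))
  expect_equal(hr$start_day, start)
  # the oracle is exact: zero spread, degenerate band, halt at the start day
  expect_equal(hr$halt_day, start)
  expect_equal(nrow(hr$trace), 1L)
  expect_true(all(hr$trace$p_value > hr$alpha))

  # a predictor with huge input sensitivity keeps the band wide; the scan
  # either exhausts (complete trace, halt_day NA) or halts much later
  wild <- make_linear_stub(50, max_days = 40, eps = 3, seed = 8)
  hr2 <- find_halt_day(wild, pl, noise = noise_spec(10, 1, seed = 3))
  expect_equal(hr2$trace$day,
               seq.int(hr2$start_day, length.out = nrow(hr2$trace)))
  if (is.na(hr2$halt_day)) {
    expect_false(any(hr2$trace$halt))
  } else {
    expect_equal(hr2$trace$day[nrow(hr2$trace)], hr2$halt_day)
    expect_true(hr2$trace$halt[nrow(hr2$trace)])
    expect_false(any(hr2$trace$halt[-nrow(hr2$trace)]))
  }

  # not-started error when no death is ever observed before the horizon
  flat <- list(list(curve = curve_of(10, 10, 10, 9, 0)))
  expect_error(find_halt_day(orc, flat, max_day = 2), "not-started")
})
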
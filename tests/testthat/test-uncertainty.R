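test_that("count perturbation is unbiased Gaussian noise clipped at zero", {
  ns <- noise_spec(n_replicates = 10, sigma = 1, seed = 3)
  x <- c(12, 11, 9, 7)
  # near-degenerate noise reproduces the input
  tiny <- noise_spec(2, sigma = 1e-12, seed = 3)
  expect_equal(perturb_input(x, tiny, 1), x, tolerance = 1e-9)
  # replicate streams are reproducible and distinct
  expect_identical(perturb_input(x, ns, 4), perturb_input(x, ns, 4))
  expect_false(identical(perturb_input(x, ns, 4), perturb_input(x, ns, 5)))
  # clipping: a zero count never goes negative
  zeros <- replicate(200, perturb_input(c(0, 0), ns, sample.int(1e6, 1)))
  expect_true(all(zeros >= 0))
  # law of large numbers: the mean perturbation vanishes
  big <- colMeans(do.call(rbind, lapply(1:10000, function(i)
    perturb_input(c(50, 50, 50), noise_spec(2, 1, seed = 7), i))))
  expect_equal(big, c(50, 50, 50), tolerance = 0.05)
})

test_that("plate uncertainty matches the closed form for a linear map", {
  x <- c(14, 13, 11, 8)
  stub <- make_linear_stub(length(x), eps = 0.01, seed = 2)
  sig <- 1
  est <- estimate_plate(stub, x, noise = noise_spec(2000, sig, seed = 11),
                        initial_count = 600)
  # every day responds identically to the (day-constant) input shift
  expected_sd <- sig * stub$eps * sqrt(sum(stub$w^2))
  expect_equal(unname(est$std_curve),
               rep(expected_sd, length(est$std_curve)), tolerance = 0.08)
  expect_equal(dim(est$replicate_curves), c(2000L, 30L - length(x) + 1L))
  expect_true(all(est$std_curve >= 0))

  # replicates all equal -> zero std, mean equals the common curve
  const <- oracle_predictor(list(curve_of(10, 5, 0)), max_days = 12)
  ep <- estimate_plate(const, c(10, 5), noise = noise_spec(20, 0.1, seed = 1))
  expect_true(all(ep$std_curve == 0))
  expect_equal(unname(ep$mean_curve), unname(ep$replicate_curves[1, ]))
  expect_error(noise_spec(n_replicates = 1), "n_replicates")
})

test_that("condition variance is the sum of plate variances (3-4-5)", {
  mk <- function(stds, means = NULL) {
    D <- length(stds)
    if (is.null(means)) means <- rep(10, D)
    structure(list(days = seq_len(D) + 4L, mean_curve = means,
                   std_curve = stds,
                   replicate_curves = matrix(means, 2, D, byrow = TRUE),
                   count_prefix = rep(12, 5), initial_count = 15, k = 4L),
              class = "plate_prediction")
  }
  band <- propagate_condition(list(mk(rep(3, 6)), mk(rep(4, 6))),
                              alpha = 0.05)
  expect_equal(unname(band$std_curve), rep(5, 6))
  # single plate passes through
  one <- propagate_condition(list(mk(c(1, 2, 3))))
  expect_equal(unname(one$std_curve), c(1, 2, 3))
  # sqrt(k) scaling for k equal plates
  four <- propagate_condition(rep(list(mk(rep(2, 3))), 4))
  expect_equal(unname(four$std_curve), rep(4, 3))
  # misaligned day axes are rejected
  b <- mk(rep(1, 3)); b$days <- b$days + 1L
  expect_error(propagate_condition(list(mk(rep(1, 3)), b)), "misaligned")
})

test_that("confidence bands use the normal quantile and clip to counts", {
  mk <- function(stds, means) structure(
    list(days = seq_along(stds), mean_curve = means, std_curve = stds,
         replicate_curves = matrix(means, 2, length(stds), byrow = TRUE),
         count_prefix = c(15, 14), initial_count = 15, k = 1L),
    class = "plate_prediction")
  pl <- mk(rep(2, 4), c(14, 10, 6, 1))
  band <- propagate_condition(list(pl), alpha = 0.05)
  # z_{alpha/2} at alpha = 5% (frozen from an independent quantile routine)
  z <- 1.95996
  expect_equal(unname(band$ci_upper - band$mean_curve)[2], 2 * z,
               tolerance = 1e-4)
  # clipping at the population bounds
  expect_lte(max(band$ci_upper), 15)
  expect_gte(min(band$ci_lower), 0)
  expect_true(all(band$ci_lower <= band$mean_curve + 1e-12))
  expect_true(all(band$ci_upper >= band$mean_curve - 1e-12))
  # halving alpha widens the band monotonically
  wider <- propagate_condition(list(pl), alpha = 0.025)
  expect_true(all(wider$ci_upper >= band$ci_upper - 1e-12))
  expect_true(all(wider$ci_lower <= band$ci_lower + 1e-12))
  # the sqrt(n) divisor halves a 4-plate band relative to its undivided form
  plates4 <- rep(list(pl), 4)
  divided <- propagate_condition(plates4, alpha = 0.05, sqrt_n = TRUE)
  undivided <- propagate_condition(plates4, alpha = 0.05, sqrt_n = FALSE)
  mid <- 2   # a day where no clipping is active
  expect_equal((undivided$ci_upper - undivided$mean_curve)[mid],
               2 * (divided$ci_upper - divided$mean_curve)[mid])
})

test_that("summed-plate variance matches joint Monte-Carlo sampling", {
  # three plates, independent perturbation streams; the error-propagation
  # band must agree with brute-force simulation of the summed prediction
  prefixes <- list(c(15, 14, 12, 9), c(12, 12, 10, 8), c(10, 9, 9, 7))
  stub <- make_linear_stub(4, eps = 0.01, seed = 5)
  N <- 10000L
  plates <- lapply(seq_along(prefixes), function(i)
    estimate_plate(stub, prefixes[[i]],
                   noise = noise_spec(N, 1, seed = 1000 * i),
                   initial_count = 600))
  band <- propagate_condition(plates, alpha = 0.05)
  joint <- Reduce(`+`, lapply(plates, `[[`, "replicate_curves"))
  joint_sd <- apply(joint, 2, sd)
  expect_equal(unname(band$std_curve), unname(joint_sd), tolerance = 0.05)
})
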
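test_that("model builds are seeded and branch ablations honour their mode", {
  isp <- tiny_image_spec()
  cfg <- model_config("bimodal_images", image_spec = isp, max_days = 20)
  m1 <- build_model(cfg, seed = 10)
  m2 <- build_model(cfg, seed = 10)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(cfg, seed = 11)
  expect_false(identical(m1$params, m3$params))

  pl <- make_plate(41)
  s <- make_samples(pl$curve, pl$frames, pl$trajectories)[[2]]

  # counts_only ignores frames entirely
  mc <- build_model(model_config("counts_only", image_spec = isp,
                                 max_days = 20), seed = 1)
  blank <- lapply(s$frame_prefix, function(f) f * 0L)
  expect_identical(
    suppressWarnings(predict_plate(mc, s$count_prefix, s$frame_prefix)),
    suppressWarnings(predict_plate(mc, s$count_prefix, blank)))

  # images_only ignores the count vector (raw output, pre-postprocessing)
  mi <- build_model(model_config("images_only", image_spec = isp,
                                 max_days = 20), seed = 1)
  raw1 <- predict_future(mi, matrix(s$count_prefix, 1), s$frame_prefix)
  raw2 <- predict_future(mi, matrix(99, 1, length(s$count_prefix)),
                         s$frame_prefix)
  expect_identical(raw1, raw2)
})

test_that("predicted curves respect clipping and monotonicity for any model", {
  isp <- tiny_image_spec()
  pl <- make_plate(42)
  samples <- make_samples(pl$curve, pl$frames, pl$trajectories)
  # untrained models with arbitrary weights must still emit valid curves
  for (seed in 1:3) {
    m <- build_model(model_config("bimodal_images", image_spec = isp,
                                  max_days = 40), seed = seed)
    for (s in samples[c(1, length(samples))]) {
      fut <- predict_plate(m, s$count_prefix, s$frame_prefix)
      expect_true(all(diff(fut) <= 1e-12))
      expect_lte(max(fut), s$count_prefix[length(s$count_prefix)])
      expect_gte(min(fut), 0)
      expect_length(fut, 40 - s$k)
    }
  }
})

test_that("a single batch can be memorised to sub-worm precision", {
  set.seed(1)
  cu <- generate_curve(simulator_params(12, a = 7, b = 16, seed = 5))
  samples <- make_samples(cu)
  cfg <- model_config("counts_only", max_days = 40)
  m <- build_model(cfg, seed = 2)
  m <- train(m, samples,
             config = train_config(epochs = 5000, learning_rate = 0.3,
                                   batch_size = length(samples),
                                   momentum = 0.9, seed = 3))
  mse_worms <- utils::tail(m$loss_record$train_mse, 1) * cfg$max_worms^2
  expect_lt(mse_worms, 0.05)
})

test_that("training descends, records losses, and is seed-deterministic", {
  law <- param_law(a_range = c(5, 10), b_range = c(12, 20))
  ds <- build_dataset(8, law = law, seed = 77, max_days = 40,
                      render = FALSE)
  cfg <- model_config("counts_only", max_days = 40)
  tc <- train_config(epochs = 8, learning_rate = 0.1, batch_size = 16,
                     seed = 4)
  m1 <- train(build_model(cfg, seed = 5), dataset_samples(ds, "train"),
              dataset_samples(ds, "val"), tc)
  expect_equal(nrow(m1$loss_record), 8L)
  expect_lt(m1$loss_record$train_mse[8], m1$loss_record$train_mse[1])
  expect_true(all(is.finite(m1$loss_record$val_mse)))
  m2 <- train(build_model(cfg, seed = 5), dataset_samples(ds, "train"),
              dataset_samples(ds, "val"), tc)
  expect_identical(m1$loss_record, m2$loss_record)
  expect_identical(m1$params, m2$params)
})

test_that("the exact-oracle predictor returns the true suffix", {
  pl <- make_plate(43)
  cu <- pl$curve
  orc <- oracle_predictor(list(cu), max_days = 40)
  s <- make_samples(cu)[[1]]
  fut <- predict_plate(orc, s$count_prefix)
  truth <- c(s$label, rep(0L, 40 - s$k - length(s$label)))
  expect_equal(unname(fut), truth)
})
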
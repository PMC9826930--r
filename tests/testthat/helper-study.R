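# The scaled-down study configuration shared by the end-to-end tests: small
# images, 40-day horizon, mortality parameters matching the evaluated
# conditions. Sizes are chosen to exercise the full pipeline on one CPU in
# minutes; see the methods vignette.

study_image_spec <- function() image_spec(side = 16L, blob_radius = 1L)

study_law <- function() param_law(a_range = c(5, 10), b_range = c(12, 20),
                                  gap_spec = gap_spec(prob = 0.5))

study_train_config <- function(seed) {
  train_config(epochs = 40L, learning_rate = 0.02, batch_size = 16L,
               momentum = 0.9, seed = seed)
}

# One 4-plate condition in the evaluation design (a in [5,10], b in [12,20],
# 10-15 worms per plate, weekend-style gaps on half the plates).
study_condition <- function(seed, isp = study_image_spec()) {
  set.seed(seed)
  a <- runif(1, 5, 10); b <- runif(1, 12, 20)
  lapply(1:4, function(i) {
    p <- suppressWarnings(
      simulator_params(sample(10:15, 1), a, b, max_days = 40L,
                       gap_spec = gap_spec(prob = 0.5),
                       seed = seed * 100 + i))
    pl <- simulate_plate(p, arena = arena_spec(isp$side, 0.6))
    list(curve = pl$curve, frames = render_sequence(pl$trajectories, isp))
  })
}

train_study_model <- function(mode, dataset, seed) {
  m <- build_model(model_config(mode, image_spec = dataset$image_spec,
                                max_days = dataset$max_days), seed = seed)
  train(m, dataset_samples(dataset, "train"), dataset_samples(dataset, "val"),
        study_train_config(seed + 10L))
}
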
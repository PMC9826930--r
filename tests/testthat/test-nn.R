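# Engine-level checks of the hand-written layers: the im2col convolution
# against a direct sliding-window oracle, and every analytic gradient
# against central finite differences.

# Direct 3x3 stride-2 pad-1 convolution + ReLU, computed pixel by pixel.
naive_conv_relu <- function(imgs, W, b, side, in_ch) {
  out_side <- (side - 1) %/% 2 + 1
  M <- nrow(imgs)
  C_out <- ncol(W)
  out <- matrix(0, M, out_side^2 * C_out)
  for (m in seq_len(M)) {
    x <- array(imgs[m, ], dim = c(side, side, in_ch))
    for (co in seq_len(C_out)) for (xo in seq_len(out_side))
      for (yo in seq_len(out_side)) {
        acc <- b[co]
        for (ci in seq_len(in_ch)) for (dx in 1:3) for (dy in 1:3) {
          yi <- 2 * yo + dy - 3; xi <- 2 * xo + dx - 3
          if (yi >= 1 && yi <= side && xi >= 1 && xi <= side) {
            wrow <- (ci - 1) * 9 + (dx - 1) * 3 + dy
            acc <- acc + x[yi, xi, ci] * W[wrow, co]
          }
        }
        out[m, (yo + (xo - 1) * out_side) + (co - 1) * out_side^2] <-
          max(acc, 0)
      }
  }
  out
}

test_that("im2col convolution matches a direct sliding-window oracle", {
  set.seed(42)
  for (case in list(list(side = 8, in_ch = 1, out_ch = 3, M = 4),
                    list(side = 6, in_ch = 2, out_ch = 2, M = 3))) {
    plan <- wormcast:::conv_plan(case$side, case$in_ch)
    W <- matrix(rnorm(9 * case$in_ch * case$out_ch), 9 * case$in_ch,
                case$out_ch)
    b <- rnorm(case$out_ch)
    X <- matrix(rnorm(case$M * case$side^2 * case$in_ch), case$M)
    got <- wormcast:::conv_fwd(X, W, b, plan)$out
    want <- naive_conv_relu(X, W, b, case$side, case$in_ch)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("masked LSTM treats front padding as a shorter sequence", {
  set.seed(7)
  p <- wormcast:::lstm_init(3, 5)
  X <- array(rnorm(2 * 4 * 3), dim = c(2, 4, 3))
  full <- wormcast:::lstm_fwd(p, X, matrix(1, 2, 4))
  # front-pad with garbage steps that the mask must ignore
  Xp <- array(rnorm(2 * 6 * 3), dim = c(2, 6, 3))
  Xp[, 3:6, ] <- X
  mask <- cbind(matrix(0, 2, 2), matrix(1, 2, 4))
  padded <- wormcast:::lstm_fwd(p, Xp, mask)
  expect_equal(padded$h, full$h, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences in every mode", {
  ns <- asNamespace("wormcast")
  isp <- image_spec(side = 8, blob_radius = 1)
  set.seed(2)
  mk <- function(k, len_label) {
    structure(list(
      count_prefix = round(runif(k + 1, 5, 12)),
      frame_prefix = replicate(k + 1, matrix(sample(0:255, 64, TRUE), 8, 8),
                               simplify = FALSE),
      coord_prefix = replicate(k + 1, matrix(runif(10, 1, 6), 5, 2),
                               simplify = FALSE),
      label = sort(sample(0:10, len_label, TRUE), decreasing = TRUE),
      k = k, initial_count = 12, plate_id = "x"), class = "model_sample")
  }
  samples <- list(mk(2, 4), mk(4, 3))
  for (mode in c("bimodal_images", "counts_only", "bimodal_coords")) {
    cfg <- model_config(mode, image_spec = isp, max_days = 10,
                        conv_channels = c(2L, 3L), image_hidden = 5L,
                        count_hidden = 4L, head_hidden = 6L)
    m <- build_model(cfg, seed = 1)
    batch <- ns$assemble_batch(samples, cfg)
    fw <- ns$forward_batch(m, batch)
    lo <- ns$masked_mse(fw$out, batch$target, batch$loss_mask)
    grads <- ns$backward_batch(m, fw, lo$grad)
    eps <- 1e-6
    for (nm in names(grads)) for (f in names(grads[[nm]])) {
      g <- grads[[nm]][[f]]
      for (i in sample(length(g), min(4, length(g)))) {
        mp <- m; mp$params[[nm]][[f]][i] <- mp$params[[nm]][[f]][i] + eps
        mm <- m; mm$params[[nm]][[f]][i] <- mm$params[[nm]][[f]][i] - eps
        num <- (ns$masked_mse(ns$forward_batch(mp, batch)$out, batch$target,
                              batch$loss_mask)$loss -
                ns$masked_mse(ns$forward_batch(mm, batch)$out, batch$target,
                              batch$loss_mask)$loss) / (2 * eps)
        expect_lt(abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])), 1e-3)
      }
    }
  }
})
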
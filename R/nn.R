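# Minimal neural-network engine used by the bimodal predictor.
#
# Everything is plain dense linear algebra driven through BLAS:
#  * 3x3 stride-2 convolutions are computed as an im2col gather (precomputed
#    index vector) followed by one dense matrix product; the backward scatter
#    is one sparse matrix product (Matrix).
#  * The LSTM is a standard i/f/g/o-gate implementation unrolled over time
#    with a per-sample validity mask (front padding), caching activations for
#    backpropagation through time.
#  * Optimisation is plain SGD on the masked mean-squared error, as used for
#    the lifespan regression.
#
# Layout conventions (all 1-based, column-major):
#  * A batch of images is a matrix [M, side^2 * C] whose columns are
#    pixel-inner (column-major within the image), channel-outer.
#  * im2col produces [M, P * 9C] with columns position-inner, then
#    (channel, kernel-offset)-outer, so a single dim<- reshape yields the
#    [M*P, 9C] matrix that multiplies the [9C, C_out] weight.

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- convolution -----------------------------------------------------------

# Precompute the gather/scatter plan of one 3x3, stride-2, pad-1 conv layer.
conv_plan <- function(side, in_ch) {
  out_side <- (side - 1L) %/% 2L + 1L
  P <- out_side^2
  q <- expand.grid(p = seq_len(P), j = 1:9, c = seq_len(in_ch))
  y_out <- (q$p - 1L) %% out_side + 1L
  x_out <- (q$p - 1L) %/% out_side + 1L
  dy <- (q$j - 1L) %% 3L + 1L
  dx <- (q$j - 1L) %/% 3L + 1L
  y_in <- 2L * y_out + dy - 3L
  x_in <- 2L * x_out + dx - 3L
  ok <- y_in >= 1L & y_in <= side & x_in >= 1L & x_in <= side
  pix <- y_in + (x_in - 1L) * side + (q$c - 1L) * side^2
  pad_slot <- side^2 * in_ch + 1L
  idx <- ifelse(ok, pix, pad_slot)          # gather index incl. zero pad slot
  # column of the im2col matrix: position-inner, (c,j)-outer
  col <- q$p + (((q$c - 1L) * 9L + q$j) - 1L) * P
  ord <- order(col)
  Gt <- Matrix::sparseMatrix(i = col[ok], j = pix[ok], x = 1,
                             dims = c(P * 9L * in_ch, side^2 * in_ch))
  list(side = side, out_side = out_side, P = P, in_ch = in_ch,
       idx = idx[ord], Gt = Gt, pad_slot = pad_slot)
}

conv_fwd <- function(X, W, b, plan) {
  M <- nrow(X)
  Xc <- cbind(X, 0)[, plan$idx, drop = FALSE]     # gather, [M, P*9C]
  dim(Xc) <- c(M * plan$P, 9L * plan$in_ch)
  Z <- Xc %*% W                                    # [M*P, C_out]
  Z <- sweep(Z, 2L, b, "+")
  A <- Z * (Z > 0)                                 # ReLU
  list(out = {
    out <- A
    dim(out) <- c(M, plan$P * ncol(W))             # pixel-inner, channel-outer
    out
  }, Xc = Xc, relu_mask = (Z > 0), M = M)
}

conv_bwd <- function(dOut, cache, W, plan) {
  M <- cache$M
  dA <- dOut
  dim(dA) <- c(M * plan$P, ncol(W))
  dZ <- dA * cache$relu_mask
  dW <- crossprod(cache$Xc, dZ)
  db <- colSums(dZ)
  dXc <- tcrossprod(dZ, W)                         # [M*P, 9C]
  dim(dXc) <- c(M, plan$P * 9L * plan$in_ch)
  dX <- as.matrix(dXc %*% plan$Gt)                 # scatter-add
  list(dX = dX, dW = dW, db = db)
}

# --- global average pooling ------------------------------------------------

gap_fwd <- function(X, P, C) {                     # X [M, P*C] -> [M, C]
  M <- nrow(X)
  dim(X) <- c(M * P, C)
  out <- rowsum(X, group = rep(seq_len(M), times = P)) / P
  out
}

gap_bwd <- function(dOut, P, C) {                  # dOut [M, C] -> [M, P*C]
  M <- nrow(dOut)
  dX <- dOut[rep(seq_len(M), times = P), , drop = FALSE] / P
  dim(dX) <- c(M, P * C)
  dX
}

# --- dense layer -----------------------------------------------------------

linear_fwd <- function(X, W, b) sweep(X %*% W, 2L, b, "+")

# --- LSTM ------------------------------------------------------------------

lstm_init <- function(D, H) {
  s <- 1 / sqrt(max(1, H))
  b <- rep(0, 4 * H)
  b[(H + 1):(2 * H)] <- 1            # forget-gate bias at 1 eases memory
  list(Wx = matrix(stats::runif(D * 4 * H, -s, s), D, 4 * H),
       Wh = matrix(stats::runif(H * 4 * H, -s, s), H, 4 * H),
       b = b)
}

# X: [B, T, D] array; mask: [B, T], 1 where the timestep is a real day.
# Returns the final hidden state and the caches needed for BPTT.
lstm_fwd <- function(p, X, mask) {
  B <- dim(X)[1]; T <- dim(X)[2]
  Hn <- ncol(p$Wh) %/% 4L
  h <- matrix(0, B, Hn); cc <- matrix(0, B, Hn)
  cache <- vector("list", T)
  for (t in seq_len(T)) {
    xt <- matrix(X[, t, ], nrow = B)
    z <- xt %*% p$Wx + h %*% p$Wh
    z <- sweep(z, 2L, p$b, "+")
    i <- sigmoid(z[, 1:Hn, drop = FALSE])
    f <- sigmoid(z[, (Hn + 1):(2 * Hn), drop = FALSE])
    g <- tanh(z[, (2 * Hn + 1):(3 * Hn), drop = FALSE])
    o <- sigmoid(z[, (3 * Hn + 1):(4 * Hn), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    m <- mask[, t]
    cache[[t]] <- list(xt = xt, h_prev = h, c_prev = cc, i = i, f = f,
                       g = g, o = o, c_new = c_new, tc = tc, m = m)
    h <- m * h_new + (1 - m) * h
    cc <- m * c_new + (1 - m) * cc
  }
  list(h = h, cache = cache, B = B, T = T, D = dim(X)[3], H = Hn)
}

lstm_bwd <- function(p, fwd, dh_final) {
  B <- fwd$B; T <- fwd$T; H <- fwd$H; D <- fwd$D
  dWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
  dWh <- matrix(0, nrow(p$Wh), ncol(p$Wh))
  db <- rep(0, length(p$b))
  dX <- array(0, dim = c(B, T, D))
  dh <- dh_final; dc <- matrix(0, B, H)
  for (t in rev(seq_len(T))) {
    cc <- fwd$cache[[t]]
    m <- cc$m
    dh_v <- m * dh                      # gradient into the updated state
    dc_v <- m * dc
    do <- dh_v * cc$tc
    dcc <- dc_v + dh_v * cc$o * (1 - cc$tc^2)
    di <- dcc * cc$g
    dg <- dcc * cc$i
    df <- dcc * cc$c_prev
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$xt, dz)
    dWh <- dWh + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dX[, t, ] <- tcrossprod(dz, p$Wx)
    # pass-through for masked steps + recurrent path for valid steps
    dh <- (1 - m) * dh + tcrossprod(dz, p$Wh)
    dc <- (1 - m) * dc + dcc * cc$f
  }
  list(Wx = dWx, Wh = dWh, b = db, dX = dX)
}

# --- masked MSE ------------------------------------------------------------

# Mean squared error over the unmasked label positions (Eq.-style mean over
# all predicted frames in the batch); returns loss and its gradient.
masked_mse <- function(pred, target, mask) {
  n <- sum(mask)
  diff <- (pred - target) * mask
  list(loss = sum(diff^2) / n, grad = 2 * diff / n)
}
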
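#' Model configuration
#'
#' The predictor is a bimodal sequence-regression network: a CNN encodes each
#' day's synthetic-domain image into an embedding and an LSTM summarises the
#' embedding sequence (spatiotemporal branch), a second LSTM encodes the
#' live-count time series, and a fully connected head regresses the
#' concatenated branch features onto the future daily counts. Ablation
#' variants drop one branch or replace the image branch with a zero-filled,
#' lexicographically sorted `max_worms x 2` coordinate matrix per day.
#'
#' @param mode One of `"bimodal_images"` (default), `"counts_only"`,
#'   `"images_only"`, `"bimodal_coords"`.
#' @param image_spec The [image_spec()] the frames are rendered with.
#' @param max_days Length of the output head (default 60): with the default
#'   relative head, output slot `j` is the count `j` days after the current
#'   day; with the absolute head, slot `d` is the count at assay day `d`.
#' @param head_mode `"relative"` (default) or `"absolute"`. The relative
#'   head predicts the remaining curve from the current day, so the
#'   recurrent features need not encode the absolute day index; the
#'   absolute head regresses onto fixed assay days.
#' @param max_worms Count normalisation constant and coordinate-matrix row
#'   count (default 16, the maximum plate population considered).
#' @param conv_channels Channel widths of the three stride-2 conv blocks.
#' @param image_hidden Hidden width of the image/coordinate branch LSTM.
#' @param count_hidden Hidden width of the count branch LSTM.
#' @param head_hidden Width of the hidden fully connected layer.
#' @return An object of class `model_config`.
#' @export
model_config <- function(mode = c("bimodal_images", "counts_only",
                                  "images_only", "bimodal_coords"),
                         image_spec = wormcast::image_spec(),
                         max_days = 60L, max_worms = 16L,
                         head_mode = c("relative", "absolute"),
                         conv_channels = c(8L, 16L, 32L),
                         image_hidden = 64L, count_hidden = 32L,
                         head_hidden = 64L) {
  mode <- match.arg(mode)
  head_mode <- match.arg(head_mode)
  stopifnot(max_days >= 2L, max_worms >= 1L, length(conv_channels) >= 1L)
  structure(list(mode = mode, image_spec = image_spec,
                 max_days = as.integer(max_days),
                 max_worms = as.integer(max_worms),
                 head_mode = head_mode,
                 conv_channels = as.integer(conv_channels),
                 image_hidden = as.integer(image_hidden),
                 count_hidden = as.integer(count_hidden),
                 head_hidden = as.integer(head_hidden)),
            class = "model_config")
}

# Map raw head output [R, max_days] to the future-day columns for days
# k+1 .. max_days.
future_from_raw <- function(config, raw, k) {
  n_fut <- config$max_days - k
  if (identical(config$head_mode, "absolute"))
    raw[, (k + 1L):config$max_days, drop = FALSE]
  else
    raw[, seq_len(n_fut), drop = FALSE]
}

uses_images <- function(config) config$mode %in% c("bimodal_images", "images_only")
uses_coords <- function(config) config$mode == "bimodal_coords"
uses_counts <- function(config) config$mode != "images_only"

head_in_dim <- function(config) {
  d <- 5L                  # skip features, see skip_features()
  if (uses_images(config) || uses_coords(config)) d <- d + config$image_hidden
  if (uses_counts(config)) d <- d + config$count_hidden
  d
}

# Skip features appended to the branch features before the head: cheap
# sufficient statistics of the count prefix that the recurrent encoder is
# slow to extract on its own -- scaled last count, day index, initial
# count, fraction still alive, and the normalised area under the prefix
# (which encodes how early the decline started). Count-derived features are
# zeroed in the image-only ablation, which must never see counts.
skip_features <- function(config, counts) {
  R <- nrow(counts); Tn <- ncol(counts)
  k <- Tn - 1L
  if (!uses_counts(config))
    return(cbind(0, rep(k / config$max_days, R), 0, 0, 0))
  last <- counts[, Tn]
  initial <- counts[, 1L]
  initial_safe <- pmax(initial, 1e-8)
  cbind(last / config$max_worms,
        k / config$max_days,
        initial / config$max_worms,
        last / initial_safe,
        rowMeans(counts) / initial_safe)
}

#' Build an (untrained) predictor
#'
#' Parameter initialisation is seeded: two builds with the same seed have
#' identical initial weights.
#'
#' @param config A [model_config()].
#' @param seed RNG seed for weight initialisation.
#' @return An object of class `worm_predictor`.
#' @export
build_model <- function(config, seed = NULL) {
  stopifnot(inherits(config, "model_config"))
  with_seed(seed, {
    params <- list()
    plans <- NULL
    if (uses_images(config)) {
      side <- config$image_spec$side
      chans <- c(1L, config$conv_channels)
      plans <- list()
      for (l in seq_along(config$conv_channels)) {
        plans[[l]] <- conv_plan(side, chans[l])
        fan <- 9L * chans[l]
        s <- 1 / sqrt(fan)
        params[[paste0("conv", l)]] <- list(
          W = matrix(stats::runif(fan * chans[l + 1L], -s, s), fan, chans[l + 1L]),
          b = rep(0, chans[l + 1L]))
        side <- plans[[l]]$out_side
      }
      emb_dim <- utils::tail(config$conv_channels, 1L)
      params$img_lstm <- lstm_init(emb_dim, config$image_hidden)
    }
    if (uses_coords(config))
      params$img_lstm <- lstm_init(2L * config$max_worms, config$image_hidden)
    if (uses_counts(config))
      # three input features per day: scaled live count, scaled day index
      # (survival hazards are time-dependent) and the day-to-day drop
      # (deaths per day -- the steepness cue of the mortality curve)
      params$cnt_lstm <- lstm_init(3L, config$count_hidden)
    fin <- head_in_dim(config)
    s1 <- 1 / sqrt(fin); s2 <- 1 / sqrt(config$head_hidden)
    params$head1 <- list(
      W = matrix(stats::runif(fin * config$head_hidden, -s1, s1),
                 fin, config$head_hidden),
      b = rep(0, config$head_hidden))
    params$head2 <- list(
      W = matrix(stats::runif(config$head_hidden * config$max_days, -s2, s2),
                 config$head_hidden, config$max_days),
      b = rep(0, config$max_days))
    structure(list(config = config, params = params, conv_plans = plans,
                   trained = FALSE, loss_record = NULL),
              class = "worm_predictor")
  })
}

#' @export
print.worm_predictor <- function(x, ...) {
  np <- if (is.null(x$params)) 0 else
    sum(unlist(rapply(x$params, length, how = "unlist")))
  cat("<worm_predictor> mode=", x$config$mode, ", ", format(np, big.mark = ","),
      " parameters, ", if (isTRUE(x$trained)) "trained" else "untrained",
      "\n", sep = "")
  invisible(x)
}

# --- batch assembly --------------------------------------------------------

# Sort a positions matrix lexicographically (x primary, y secondary) and
# zero-fill to max_worms rows; returns a flat vector of length 2*max_worms.
coords_vector <- function(pos, max_worms, side) {
  out <- matrix(0, max_worms, 2L)
  if (!is.null(pos) && nrow(pos) > 0L) {
    pos <- pos[order(pos[, 1L], pos[, 2L]), , drop = FALSE]
    n <- min(nrow(pos), max_worms)
    out[seq_len(n), ] <- pos[seq_len(n), , drop = FALSE] / side
  }
  as.vector(t(out))                                # x1 y1 x2 y2 ...
}

# Assemble a list of model_sample into dense training tensors. Prefixes are
# front-padded to the longest prefix in the batch; the target is the absolute
# per-day count vector (0 after extinction) masked to days > k.
assemble_batch <- function(samples, config) {
  B <- length(samples)
  lens <- vapply(samples, function(s) length(s$count_prefix), integer(1))
  T <- max(lens)
  D <- config$max_days
  mask_t <- matrix(0, B, T)
  Xcnt <- array(0, dim = c(B, T, 3L))
  target <- matrix(0, B, D)
  loss_mask <- matrix(0, B, D)
  for (b in seq_len(B)) {
    s <- samples[[b]]
    off <- T - lens[b]
    mask_t[b, (off + 1L):T] <- 1
    Xcnt[b, (off + 1L):T, 1L] <- s$count_prefix / config$max_worms
    Xcnt[b, (off + 1L):T, 2L] <- (seq_len(lens[b]) - 1L) / config$max_days
    Xcnt[b, (off + 1L):T, 3L] <- c(0, -diff(s$count_prefix)) / config$max_worms
    if (identical(config$head_mode, "absolute")) {
      lab_days <- s$k + seq_along(s$label)         # absolute days k+1..end
      lab_days <- lab_days[lab_days <= D]
      target[b, lab_days] <- s$label[seq_along(lab_days)] / config$max_worms
      loss_mask[b, (s$k + 1L):D] <- 1              # 0 after extinction is real
    } else {
      j <- seq_len(min(length(s$label), D))        # slot j = day k + j
      target[b, j] <- s$label[j] / config$max_worms
      loss_mask[b, ] <- 1                          # later slots are real 0s
    }
  }
  skip <- do.call(rbind, lapply(samples, function(s)
    skip_features(config, matrix(s$count_prefix, nrow = 1L))))
  out <- list(B = B, T = T, lens = lens, mask_t = mask_t, Xcnt = Xcnt,
              target = target, loss_mask = loss_mask, skip = skip)
  if (uses_images(config)) {
    side2 <- config$image_spec$side^2
    nval <- sum(lens)
    Fmat <- matrix(0, nval, side2)
    slot <- matrix(0L, B, T)                       # row of Fmat per (b, t)
    r <- 0L
    for (b in seq_len(B)) {
      s <- samples[[b]]; off <- T - lens[b]
      for (tt in seq_len(lens[b])) {
        r <- r + 1L
        Fmat[r, ] <- as.vector(s$frame_prefix[[tt]]) / 255
        slot[b, off + tt] <- r
      }
    }
    out$Fmat <- Fmat; out$slot <- slot
  }
  if (uses_coords(config)) {
    Dc <- 2L * config$max_worms
    Xcoord <- array(0, dim = c(B, T, Dc))
    for (b in seq_len(B)) {
      s <- samples[[b]]; off <- T - lens[b]
      for (tt in seq_len(lens[b]))
        Xcoord[b, off + tt, ] <- coords_vector(s$coord_prefix[[tt]],
                                               config$max_worms,
                                               config$image_spec$side)
    }
    out$Xcoord <- Xcoord
  }
  out
}

# --- forward / backward ----------------------------------------------------

# Run the conv stack on a stack of flattened frames [M, side^2].
conv_stack_fwd <- function(predictor, Fmat) {
  cfg <- predictor$config
  caches <- list(); X <- Fmat
  for (l in seq_along(cfg$conv_channels)) {
    cc <- conv_fwd(X, predictor$params[[paste0("conv", l)]]$W,
                   predictor$params[[paste0("conv", l)]]$b,
                   predictor$conv_plans[[l]])
    caches[[l]] <- cc
    X <- cc$out
  }
  P <- predictor$conv_plans[[length(caches)]]$P
  C <- utils::tail(cfg$conv_channels, 1L)
  list(emb = gap_fwd(X, P, C), caches = caches, P = P, C = C)
}

conv_stack_bwd <- function(predictor, stack, dEmb) {
  cfg <- predictor$config
  grads <- list()
  dX <- gap_bwd(dEmb, stack$P, stack$C)
  for (l in rev(seq_along(cfg$conv_channels))) {
    bb <- conv_bwd(dX, stack$caches[[l]],
                   predictor$params[[paste0("conv", l)]]$W,
                   predictor$conv_plans[[l]])
    grads[[paste0("conv", l)]] <- list(W = bb$dW, b = bb$db)
    dX <- bb$dX
  }
  grads
}

forward_batch <- function(predictor, batch) {
  cfg <- predictor$config
  feats <- list(); cache <- list(batch = batch)
  if (uses_images(cfg)) {
    stack <- conv_stack_fwd(predictor, batch$Fmat)
    C <- stack$C
    E <- array(0, dim = c(batch$B, batch$T, C))
    for (b in seq_len(batch$B)) {
      rows <- batch$slot[b, ]
      valid <- which(rows > 0L)
      E[b, valid, ] <- stack$emb[rows[valid], , drop = FALSE]
    }
    cache$stack <- stack
    cache$img_lstm <- lstm_fwd(predictor$params$img_lstm, E, batch$mask_t)
    feats$img <- cache$img_lstm$h
  }
  if (uses_coords(cfg)) {
    cache$img_lstm <- lstm_fwd(predictor$params$img_lstm, batch$Xcoord,
                               batch$mask_t)
    feats$img <- cache$img_lstm$h
  }
  if (uses_counts(cfg)) {
    cache$cnt_lstm <- lstm_fwd(predictor$params$cnt_lstm, batch$Xcnt,
                               batch$mask_t)
    feats$cnt <- cache$cnt_lstm$h
  }
  feats$skip <- batch$skip
  Fcat <- do.call(cbind, feats)
  H1 <- linear_fwd(Fcat, predictor$params$head1$W, predictor$params$head1$b)
  A1 <- H1 * (H1 > 0)
  out <- linear_fwd(A1, predictor$params$head2$W, predictor$params$head2$b)
  cache$Fcat <- Fcat; cache$A1 <- A1; cache$relu1 <- (H1 > 0)
  list(out = out, cache = cache)
}

backward_batch <- function(predictor, fw, dOut) {
  cfg <- predictor$config
  cache <- fw$cache; batch <- cache$batch
  grads <- list()
  grads$head2 <- list(W = crossprod(cache$A1, dOut), b = colSums(dOut))
  dA1 <- tcrossprod(dOut, predictor$params$head2$W) * cache$relu1
  grads$head1 <- list(W = crossprod(cache$Fcat, dA1), b = colSums(dA1))
  dF <- tcrossprod(dA1, predictor$params$head1$W)
  col <- 0L
  if (uses_images(cfg) || uses_coords(cfg)) {
    Hs <- cfg$image_hidden
    dh_img <- dF[, (col + 1L):(col + Hs), drop = FALSE]; col <- col + Hs
    lb <- lstm_bwd(predictor$params$img_lstm, cache$img_lstm, dh_img)
    grads$img_lstm <- lb[c("Wx", "Wh", "b")]
    if (uses_images(cfg)) {
      C <- cache$stack$C
      dEmb <- matrix(0, nrow(cache$stack$emb), C)
      for (b in seq_len(batch$B)) {
        rows <- batch$slot[b, ]
        valid <- which(rows > 0L)
        dEmb[rows[valid], ] <- matrix(lb$dX[b, valid, ], ncol = C)
      }
      grads <- c(grads, conv_stack_bwd(predictor, cache$stack, dEmb))
    }
  }
  if (uses_counts(cfg)) {
    Hc <- cfg$count_hidden
    dh_cnt <- dF[, (col + 1L):(col + Hc), drop = FALSE]
    lb <- lstm_bwd(predictor$params$cnt_lstm, cache$cnt_lstm, dh_cnt)
    grads$cnt_lstm <- lb[c("Wx", "Wh", "b")]
  }
  grads
}

sgd_step <- function(params, grads, lr, momentum = 0, velocity = NULL) {
  if (momentum > 0 && is.null(velocity)) velocity <- list()
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) {
      g <- grads[[nm]][[f]]
      if (momentum > 0) {
        v <- velocity[[nm]][[f]]
        v <- if (is.null(v)) g else momentum * v + g
        velocity[[nm]][[f]] <- v
        g <- v
      }
      params[[nm]][[f]] <- params[[nm]][[f]] - lr * g
    }
  }
  list(params = params, velocity = velocity)
}

# --- training --------------------------------------------------------------

#' Training configuration
#'
#' The full-scale default recipe is 100 epochs of
#' plain SGD at learning rate 0.001 with batches of 16 samples, minimising
#' the mean squared error over the predicted future counts. At full scale
#' (tens of thousands of samples) that recipe takes hundreds of thousands of
#' SGD steps; small-scale runs should raise the learning rate and enable
#' classical momentum to reach a comparable optimisation depth in far fewer
#' steps.
#'
#' @param epochs Number of passes over the training set.
#' @param learning_rate SGD step size.
#' @param batch_size Samples per gradient step.
#' @param momentum Classical momentum coefficient in `[0, 1)`; 0 (default)
#'   is plain SGD.
#' @param input_noise_sd Standard deviation (worms) of Gaussian noise added
#'   to the training count prefixes (clipped at 0), 0 to disable. At
#'   prediction time the uncertainty estimator feeds the model
#'   noise-perturbed counts, so training under the same perturbation keeps
#'   those inputs in-distribution and regularises the fit.
#' @param seed RNG seed controlling shuffling (and, with a freshly built
#'   model, the whole run).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, learning_rate = 0.001,
                         batch_size = 16L, momentum = 0,
                         input_noise_sd = 0, seed = NULL) {
  stopifnot(epochs >= 1L, learning_rate > 0, batch_size >= 1L,
            momentum >= 0, momentum < 1, input_noise_sd >= 0)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), momentum = momentum,
                 input_noise_sd = input_noise_sd, seed = seed),
            class = "train_config")
}

batch_loss <- function(predictor, samples, batch_size) {
  tot <- 0; n <- 0
  for (idx in split(seq_along(samples),
                    ceiling(seq_along(samples) / batch_size))) {
    batch <- assemble_batch(samples[idx], predictor$config)
    fw <- forward_batch(predictor, batch)
    m <- sum(batch$loss_mask)
    tot <- tot + masked_mse(fw$out, batch$target, batch$loss_mask)$loss * m
    n <- n + m
  }
  tot / n
}

#' Train a predictor
#'
#' Minimises the masked mean squared error between predicted and labelled
#' future counts (counts scaled by `1/max_worms`) with plain SGD. Keeps the
#' parameters of the best-validation epoch.
#'
#' @param predictor A `worm_predictor` from [build_model()].
#' @param train_samples,val_samples Lists of `model_sample` (e.g. from
#'   [dataset_samples()]); `val_samples` may be empty, in which case the
#'   final-epoch parameters are kept.
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return The trained `worm_predictor`, with `$loss_record` (data frame
#'   `epoch`, `train_mse`, `val_mse`) attached.
#' @export
train <- function(predictor, train_samples, val_samples = list(),
                  config = train_config(), verbose = FALSE) {
  stopifnot(inherits(predictor, "worm_predictor"),
            inherits(config, "train_config"))
  if (length(train_samples) == 0L) stop("empty training set", call. = FALSE)
  with_seed(config$seed, {
    best_val <- Inf; best_params <- predictor$params
    rec <- data.frame(epoch = integer(0), train_mse = numeric(0),
                      val_mse = numeric(0))
    n <- length(train_samples)
    velocity <- NULL
    for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      ep_loss <- 0; ep_n <- 0
      for (idx in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        bs <- train_samples[idx]
        if (config$input_noise_sd > 0)
          bs <- lapply(bs, function(s) {
            s$count_prefix <- pmax(0, s$count_prefix +
                                     stats::rnorm(length(s$count_prefix), 0,
                                                  config$input_noise_sd))
            s
          })
        batch <- assemble_batch(bs, predictor$config)
        fw <- forward_batch(predictor, batch)
        lo <- masked_mse(fw$out, batch$target, batch$loss_mask)
        if (!is.finite(lo$loss))
          stop("training diverged: non-finite loss at epoch ", ep, call. = FALSE)
        grads <- backward_batch(predictor, fw, lo$grad)
        up <- sgd_step(predictor$params, grads, config$learning_rate,
                       config$momentum, velocity)
        predictor$params <- up$params
        velocity <- up$velocity
        m <- sum(batch$loss_mask)
        ep_loss <- ep_loss + lo$loss * m; ep_n <- ep_n + m
      }
      tr <- ep_loss / ep_n
      va <- if (length(val_samples) > 0L)
        batch_loss(predictor, val_samples, config$batch_size) else NA_real_
      rec <- rbind(rec, data.frame(epoch = ep, train_mse = tr, val_mse = va))
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %s", ep, tr,
                        ifelse(is.na(va), "-", sprintf("%.5f", va))))
      if (!is.na(va) && va < best_val) {
        best_val <- va; best_params <- predictor$params
      }
    }
    if (length(val_samples) > 0L) predictor$params <- best_params
    predictor$trained <- TRUE
    predictor$loss_record <- rec
    predictor
  })
}

# --- prediction ------------------------------------------------------------

# Encode the image (or coordinate) branch of one prefix; the result can be
# reused across Monte-Carlo count perturbations, which never touch frames.
encode_image_branch <- function(predictor, frame_prefix = NULL,
                                coord_prefix = NULL) {
  cfg <- predictor$config
  if (uses_images(cfg)) {
    stopifnot(!is.null(frame_prefix))
    Tn <- length(frame_prefix)
    Fmat <- t(vapply(frame_prefix, function(f) as.vector(f) / 255,
                     numeric(cfg$image_spec$side^2)))
    stack <- conv_stack_fwd(predictor, Fmat)
    E <- array(0, dim = c(1L, Tn, stack$C))
    E[1L, , ] <- stack$emb
    lstm_fwd(predictor$params$img_lstm, E, matrix(1, 1L, Tn))$h
  } else if (uses_coords(cfg)) {
    stopifnot(!is.null(coord_prefix))
    Tn <- length(coord_prefix)
    Dc <- 2L * cfg$max_worms
    X <- array(0, dim = c(1L, Tn, Dc))
    for (tt in seq_len(Tn))
      X[1L, tt, ] <- coords_vector(coord_prefix[[tt]], cfg$max_worms,
                                   cfg$image_spec$side)
    lstm_fwd(predictor$params$img_lstm, X, matrix(1, 1L, Tn))$h
  } else NULL
}

# Raw head output for a batch of (possibly perturbed) count prefixes sharing
# one image feature. counts: matrix [R, T] in worm units (real-valued).
predict_raw <- function(predictor, counts, img_feat = NULL) {
  cfg <- predictor$config
  R <- nrow(counts); Tn <- ncol(counts)
  feats <- list()
  if (uses_images(cfg) || uses_coords(cfg)) {
    stopifnot(!is.null(img_feat))
    feats$img <- img_feat[rep(1L, R), , drop = FALSE]
  }
  if (uses_counts(cfg)) {
    X <- array(0, dim = c(R, Tn, 3L))
    X[, , 1L] <- counts / cfg$max_worms
    X[, , 2L] <- matrix((seq_len(Tn) - 1L) / cfg$max_days, R, Tn,
                        byrow = TRUE)
    if (Tn > 1L)
      X[, 2:Tn, 3L] <- -(counts[, 2:Tn, drop = FALSE] -
                           counts[, 1:(Tn - 1L), drop = FALSE]) /
        cfg$max_worms
    feats$cnt <- lstm_fwd(predictor$params$cnt_lstm, X,
                          matrix(1, R, Tn))$h
  }
  feats$skip <- skip_features(cfg, counts)
  Fcat <- do.call(cbind, feats)
  A1 <- linear_fwd(Fcat, predictor$params$head1$W, predictor$params$head1$b)
  A1 <- A1 * (A1 > 0)
  out <- linear_fwd(A1, predictor$params$head2$W, predictor$params$head2$b)
  out * cfg$max_worms                              # back to worm units
}

#' Raw future-count prediction (generic)
#'
#' Maps a batch of (possibly perturbed) count prefixes, sharing one set of
#' frames/coordinates, to raw predicted counts for absolute days
#' `1..max_days` in worm units. Methods exist for trained networks
#' (`worm_predictor`) and for the exact-oracle stub used in validation
#' ([oracle_predictor()]).
#'
#' @param predictor The predictor object.
#' @param counts Numeric matrix `[R, T]`: R replicate count prefixes.
#' @param frame_prefix,coord_prefix Shared per-day frames / positions.
#' @return Numeric matrix `[R, max_days]` of raw (un-postprocessed) counts.
#' @export
predict_future <- function(predictor, counts, frame_prefix = NULL,
                           coord_prefix = NULL) {
  UseMethod("predict_future")
}

#' @export
predict_future.worm_predictor <- function(predictor, counts,
                                          frame_prefix = NULL,
                                          coord_prefix = NULL) {
  img_feat <- encode_image_branch(predictor, frame_prefix, coord_prefix)
  predict_raw(predictor, counts, img_feat)
}

#' Exact-oracle predictor stub
#'
#' A drop-in replacement for a trained network that already knows the true
#' curves: given a (possibly noise-perturbed) count prefix it returns the
#' stored reference curve whose prefix is closest in squared error. It is
#' used to validate the evaluation machinery -- with it, predictions are
#' exact, uncertainty collapses to zero and the halting criterion fires
#' immediately.
#'
#' @param curves List of complete [lifespan_curve()]s the oracle may answer
#'   with.
#' @param max_days Output horizon.
#' @return An object of classes `oracle_predictor`, usable wherever a
#'   trained `worm_predictor` is accepted (count-only mode).
#' @export
oracle_predictor <- function(curves, max_days = 60L) {
  stopifnot(all(vapply(curves, inherits, logical(1), "lifespan_curve")))
  abs_curves <- lapply(curves, function(cu) {
    full <- c(cu$live_counts, rep(0L, max_days + 1L - length(cu$live_counts)))
    full[seq_len(max_days + 1L)]                   # days 0..max_days
  })
  structure(list(abs_curves = abs_curves,
                 config = model_config(mode = "counts_only",
                                       max_days = max_days,
                                       head_mode = "absolute"),
                 trained = TRUE),
            class = c("oracle_predictor", "worm_predictor"))
}

#' @export
predict_future.oracle_predictor <- function(predictor, counts,
                                            frame_prefix = NULL,
                                            coord_prefix = NULL) {
  D <- predictor$config$max_days
  Tn <- ncol(counts)
  out <- matrix(0, nrow(counts), D)
  for (r in seq_len(nrow(counts))) {
    sse <- vapply(predictor$abs_curves, function(ac)
      sum((ac[seq_len(Tn)] - counts[r, ])^2), numeric(1))
    best <- predictor$abs_curves[[which.min(sse)]]
    out[r, ] <- best[2:(D + 1L)]                   # days 1..max_days
  }
  out
}

# Clip to [0, initial], then enforce a non-increasing curve starting from the
# last observed count (running minimum).
postprocess_curve <- function(raw_future, last_obs, initial) {
  x <- pmin(pmax(raw_future, 0), initial)
  cummin(c(last_obs, x))[-1L]
}

#' Predict the future counts of one plate
#'
#' Runs the network on the observed prefix and post-processes the raw
#' regression output into a valid survival-curve suffix: counts are clipped
#' to `[0, initial_count]` and made non-increasing starting from the last
#' observed count.
#'
#' @param predictor A trained `worm_predictor`.
#' @param count_prefix Numeric vector of live counts for days `0..k`.
#' @param frame_prefix List of frames for the same days (image modes).
#' @param coord_prefix List of position matrices for the same days
#'   (coordinate mode).
#' @param initial_count Plate population; defaults to `count_prefix[1]`.
#' @return Numeric vector of predicted counts for days `k+1 .. max_days`.
#' @export
predict_plate <- function(predictor, count_prefix, frame_prefix = NULL,
                          coord_prefix = NULL,
                          initial_count = count_prefix[1L]) {
  stopifnot(inherits(predictor, "worm_predictor"), length(count_prefix) >= 1L)
  cfg <- predictor$config
  k <- length(count_prefix) - 1L
  if (k + 1L > cfg$max_days)
    stop("prefix extends past the model horizon", call. = FALSE)
  if (all(count_prefix == count_prefix[1L]))
    warning("no death observed yet (k < first drop day); prediction unreliable")
  raw <- predict_future(predictor, matrix(count_prefix, nrow = 1L),
                        frame_prefix, coord_prefix)
  future_days <- (k + 1L):cfg$max_days
  fut <- postprocess_curve(future_from_raw(cfg, raw, k)[1L, ],
                           last_obs = count_prefix[k + 1L],
                           initial = initial_count)
  names(fut) <- future_days
  fut
}
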
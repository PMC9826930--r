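# Shared fixture builders; everything is generated in code at test time.

tiny_image_spec <- function() image_spec(side = 16L, blob_radius = 1L)

tiny_arena <- function() arena_spec(side = 16L, radius_frac = 0.6)

# One simulated plate (curve + trajectories + frames) at test scale.
make_plate <- function(seed, n = 12L, a = 7, b = 16, gaps = NULL,
                       spec = tiny_image_spec()) {
  params <- suppressWarnings(
    simulator_params(n, a, b, max_days = 40L, gap_spec = gaps, seed = seed))
  pl <- simulate_plate(params, arena = tiny_arena())
  pl$frames <- render_sequence(pl$trajectories, spec)
  pl
}

# A 4-plate condition in the design range of the evaluation protocol.
make_condition <- function(seed, a = NULL, b = NULL, n_plates = 4L,
                           gaps = gap_spec(prob = 0.5),
                           spec = tiny_image_spec()) {
  set.seed(seed)
  if (is.null(a)) a <- runif(1, 5, 10)
  if (is.null(b)) b <- runif(1, 12, 20)
  lapply(seq_len(n_plates), function(i)
    make_plate(seed * 100 + i, n = sample(10:15, 1), a = a, b = b,
               gaps = gaps, spec = spec))
}

# Deterministic hand-built curve helper.
curve_of <- function(...) lifespan_curve(c(...))

# Expand a count curve into per-worm survival records (time, status) for
# cross-checks against survival::survdiff.
curve_to_surv_df <- function(counts, group) {
  ev <- curve_to_events(counts)
  time <- rep(ev$day, ev$deaths)
  status <- rep(1L, length(time))
  cens <- attr(ev, "censored")
  if (cens > 0) {
    time <- c(time, rep(length(counts) - 1L, cens))
    status <- c(status, rep(0L, cens))
  }
  data.frame(time = time, status = status, group = group)
}

# Independent brute-force Mantel-Cox log-rank from first principles, used as
# the oracle for the in-package implementation.
brute_force_logrank <- function(ca, cb) {
  deaths <- function(cc, d) if (d >= 1 && d <= length(cc) - 1) cc[d] - cc[d + 1] else 0
  at_risk <- function(cc, d) if (d <= length(cc) - 1) cc[d] else 0
  days <- seq_len(max(length(ca), length(cb)))
  num <- 0; den <- 0
  for (d in days) {
    d1 <- deaths(ca, d); d2 <- deaths(cb, d)
    if (d1 + d2 == 0) next
    n1 <- at_risk(ca, d); n2 <- at_risk(cb, d)
    nj <- n1 + n2; dj <- d1 + d2
    num <- num + (d1 - dj * n1 / nj)
    if (nj > 1)
      den <- den + dj * (n1 / nj) * (n2 / nj) * (nj - dj) / (nj - 1)
  }
  if (den <= 0) return(list(stat = 0, p = 1))
  stat <- num^2 / den
  list(stat = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

# A linear stub predictor: day-d output (6 - 0.02 d) - eps * (w . x). The
# outputs sit strictly below the observed counts, stay positive, and
# decrease in d, so clip + running-minimum post-processing is the identity
# and the closed-form noise response sigma * eps * ||w|| is exact. Large
# eps values instead give a predictor with huge input sensitivity, whose
# uncertainty band never collapses.
make_linear_stub <- function(Tn, max_days = 30L, eps = 0.01, seed = 1) {
  set.seed(seed)
  w <- rnorm(Tn)
  structure(list(config = model_config("counts_only", max_days = max_days,
                                       head_mode = "absolute"),
                 w = w, eps = eps),
            class = c("linear_stub", "worm_predictor"))
}

predict_future.linear_stub <- function(predictor, counts,
                                       frame_prefix = NULL,
                                       coord_prefix = NULL) {
  D <- predictor$config$max_days
  base <- 6 - 0.02 * seq_len(D)
  w <- predictor$w[seq_len(min(length(predictor$w), ncol(counts)))]
  shift <- as.numeric(counts[, seq_along(w), drop = FALSE] %*% w) *
    predictor$eps
  outer(shift, base, function(s, b) b - s)
}
registerS3method("predict_future", "linear_stub", predict_future.linear_stub,
                 envir = asNamespace("wormcast"))

# Random non-increasing integer curve with at least one death.
random_curve <- function(n = NULL, len = NULL) {
  if (is.null(n)) n <- sample(8:15, 1)
  if (is.null(len)) len <- sample(5:20, 1)
  repeat {
    drops <- rmultinom(1, n, prob = runif(len))[, 1]
    counts <- n - cumsum(drops)
    counts <- c(n, counts)
    if (any(diff(counts) < 0)) return(as.integer(counts))
  }
}
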
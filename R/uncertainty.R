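#' Input-perturbation noise settings
#'
#' The network returns a single point prediction; its uncertainty is
#' approximated by the spread of predictions over `n_replicates` copies of
#' the input with i.i.d. Gaussian noise added. The noise targets the count
#' sequence (standard deviation in worms); frames are left untouched by
#' default because unit-variance intensity noise is ill-defined for flat
#' blob images. An optional position-jitter mode perturbs blob centres
#' instead (`target = "positions"`, sigma in pixels) for image-mode models.
#'
#' @param n_replicates Number of perturbed inputs N (default 30, `>= 2`).
#' @param sigma Noise standard deviation (default 1, matching a standard
#'   normal perturbation of the counts).
#' @param target `"counts"` (default) or `"positions"`.
#' @param seed Optional base seed; replicate `i` uses stream `seed + i`.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(n_replicates = 30L, sigma = 1, target = c("counts",
                                                                 "positions"),
                       seed = NULL) {
  target <- match.arg(target)
  n_replicates <- as.integer(n_replicates)
  stopifnot(n_replicates >= 2L, sigma > 0)
  structure(list(n_replicates = n_replicates, sigma = sigma, target = target,
                 seed = seed), class = "noise_spec")
}

#' Perturb a count prefix with Gaussian noise
#'
#' Adds an independent draw from `Normal(0, sigma^2)` to every element and
#' clips the result at 0 (counts cannot be negative). The perturbed counts
#' are deliberately left real-valued: the model consumes scaled continuous
#' counts.
#'
#' @param count_prefix Numeric vector of observed live counts.
#' @param noise A [noise_spec()].
#' @param replicate Replicate index (seeds stream `seed + replicate` when
#'   the noise settings carry a seed).
#' @return Perturbed numeric vector of the same length, all `>= 0`.
#' @export
perturb_input <- function(count_prefix, noise, replicate = 1L) {
  stopifnot(inherits(noise, "noise_spec"))
  seed <- if (is.null(noise$seed)) NULL else noise$seed + as.integer(replicate)
  with_seed(seed,
            pmax(0, count_prefix + stats::rnorm(length(count_prefix),
                                                0, noise$sigma)))
}

#' Per-plate prediction with Monte-Carlo uncertainty
#'
#' Generates `N` noisy copies of the observed input, predicts the future
#' curve for each, and summarises them by the per-day sample mean and sample
#' standard deviation (with `N - 1` denominator). Frames are encoded once
#' and reused across replicates when the noise targets the counts.
#'
#' @param predictor A trained `worm_predictor`.
#' @param count_prefix Observed live counts for days `0..k`.
#' @param frame_prefix Frames for the same days (image modes).
#' @param noise A [noise_spec()].
#' @param coord_prefix Position matrices for the same days (coordinate mode;
#'   also required for position-jitter noise).
#' @param initial_count Plate population; defaults to `count_prefix[1]`.
#' @return An object of class `plate_prediction`: list with `days` (future
#'   day indices `k+1..max_days`), `mean_curve`, `std_curve`,
#'   `replicate_curves` (`[N, length(days)]`), the observed `count_prefix`
#'   and `initial_count`.
#' @export
estimate_plate <- function(predictor, count_prefix, frame_prefix = NULL,
                           noise = noise_spec(), coord_prefix = NULL,
                           initial_count = count_prefix[1L]) {
  stopifnot(inherits(predictor, "worm_predictor"),
            inherits(noise, "noise_spec"))
  cfg <- predictor$config
  k <- length(count_prefix) - 1L
  future_days <- (k + 1L):cfg$max_days
  N <- noise$n_replicates
  last_obs <- count_prefix[k + 1L]
  if (noise$target == "counts") {
    pert <- do.call(rbind, lapply(seq_len(N), function(i)
      perturb_input(count_prefix, noise, i)))
    raw <- predict_future(predictor, pert, frame_prefix, coord_prefix)
  } else {
    # position jitter: re-render frames with jittered blob centres
    stopifnot(!is.null(coord_prefix))
    raw <- matrix(0, N, cfg$max_days)
    for (i in seq_len(N)) {
      seed <- if (is.null(noise$seed)) NULL else noise$seed + i
      jit <- with_seed(seed, lapply(coord_prefix, function(p) {
        q <- p + matrix(stats::rnorm(length(p), 0, noise$sigma), nrow(p), 2L)
        pmin(pmax(q, 0), cfg$image_spec$side - 1)
      }))
      fp <- lapply(jit, render_frame, spec = cfg$image_spec)
      raw[i, ] <- predict_future(predictor, matrix(count_prefix, nrow = 1L),
                                 fp, jit)[1L, ]
    }
  }
  reps <- future_from_raw(cfg, raw, k)
  for (i in seq_len(N))
    reps[i, ] <- postprocess_curve(reps[i, ], last_obs, initial_count)
  mean_curve <- colMeans(reps)
  std_curve <- apply(reps, 2L, stats::sd)          # N - 1 denominator
  structure(list(days = future_days, mean_curve = mean_curve,
                 std_curve = std_curve, replicate_curves = reps,
                 count_prefix = count_prefix,
                 initial_count = initial_count, k = k),
            class = "plate_prediction")
}

#' @export
print.plate_prediction <- function(x, ...) {
  cat("<plate_prediction> k=", x$k, ", ", nrow(x$replicate_curves),
      " replicates, days ", min(x$days), "..", max(x$days), "\n", sep = "")
  invisible(x)
}

#' Propagate per-plate uncertainty to the condition level
#'
#' A condition's count is the sum of its plates' counts, so the condition
#' mean is the sum of plate means and -- the partial derivatives of a sum
#' all being 1 -- the condition variance is the sum of plate variances:
#' `S_C = sqrt(sum_k S_Pk^2)`. The confidence interval is
#' `C +/- z_(alpha/2) * S_C / sqrt(n)` with `n` the number of plates; the
#' `sqrt(n)` divisor is part of the method's formulation (set
#' `sqrt_n = FALSE` to drop it, which widens the band).
#'
#' @param plates List of `plate_prediction`, one per plate, sharing the same
#'   current day `k` and day axis.
#' @param alpha Significance level of the interval (default 0.05).
#' @param sqrt_n Divide `S_C` by `sqrt(n)` as in the method's formulation
#'   (default `TRUE`).
#' @return An object of class `condition_band`: list with `days`,
#'   `mean_curve`, `std_curve`, `ci_lower`, `ci_upper` (clipped to
#'   `[0, total initial count]`), `obs_prefix` (summed observed counts for
#'   days `0..k`), `total_initial`, `alpha`, `n_plates`.
#' @export
propagate_condition <- function(plates, alpha = 0.05, sqrt_n = TRUE) {
  stopifnot(length(plates) >= 1L,
            all(vapply(plates, inherits, logical(1), "plate_prediction")))
  days <- plates[[1L]]$days
  for (p in plates)
    if (!identical(p$days, days))
      stop("plates have misaligned day axes", call. = FALSE)
  n <- length(plates)
  mean_curve <- Reduce(`+`, lapply(plates, `[[`, "mean_curve"))
  std_curve <- sqrt(Reduce(`+`, lapply(plates,
                                       function(p) p$std_curve^2)))
  total_initial <- sum(vapply(plates, `[[`, numeric(1), "initial_count"))
  z <- stats::qnorm(1 - alpha / 2)
  half <- z * std_curve / if (sqrt_n) sqrt(n) else 1
  ci_lower <- pmin(pmax(mean_curve - half, 0), total_initial)
  ci_upper <- pmin(pmax(mean_curve + half, 0), total_initial)
  obs_prefix <- Reduce(`+`, lapply(plates, `[[`, "count_prefix"))
  structure(list(days = days, mean_curve = mean_curve, std_curve = std_curve,
                 ci_lower = ci_lower, ci_upper = ci_upper,
                 obs_prefix = obs_prefix, total_initial = total_initial,
                 alpha = alpha, n_plates = n),
            class = "condition_band")
}

#' @export
print.condition_band <- function(x, ...) {
  cat("<condition_band> ", x$n_plates, " plates, alpha=", x$alpha,
      ", days ", min(x$days), "..", max(x$days), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.condition_band <- function(x, ...) {
  data.frame(day = x$days, mean = x$mean_curve, std = x$std_curve,
             ci_lower = x$ci_lower, ci_upper = x$ci_upper)
}
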
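#' First day the curve falls
#'
#' The earliest admissible prediction point: the first day a worm dies. The
#' model is only ever asked to predict from day `k >= first_drop_day(curve)`,
#' because before any death the curve carries no information about the
#' plate's mortality parameters.
#'
#' @param curve A [lifespan_curve()].
#' @return Smallest day index `d` with `live_counts[d] < initial_count`.
#' @export
first_drop_day <- function(curve) {
  stopifnot(inherits(curve, "lifespan_curve"))
  d <- which(curve$live_counts < curve$initial_count)
  if (length(d) == 0L)
    stop("curve never falls: no death observed (no-drop error)", call. = FALSE)
  curve$days[d[1L]]
}

#' Build training samples from one curve
#'
#' From each simulated curve one sample is produced per remaining day: for
#' every current-day index `k` from the first drop day to the day before
#' extinction, the inputs are the counts and frames for days `0..k` and the
#' label is the count suffix for days `k+1..end`. A curve extinct at day `E`
#' with first drop at day `F` therefore yields `E - F` samples.
#'
#' @param curve A [lifespan_curve()].
#' @param frames The matching `frame_sequence` (same day axis), or `NULL`
#'   for count-only samples.
#' @param trajectories Optional `worm_trajectories`; when given, each sample
#'   also carries the per-day worm position matrices (`coord_prefix`) needed
#'   by the coordinate-input model variant.
#' @return List of `model_sample` objects with fields `count_prefix` (days
#'   `0..k`), `frame_prefix` (list of frames, same days), `label` (integer
#'   counts for days `k+1..end`), `k`, `initial_count`, `plate_id`.
#' @export
make_samples <- function(curve, frames = NULL, trajectories = NULL) {
  stopifnot(inherits(curve, "lifespan_curve"))
  if (!is.null(frames)) {
    stopifnot(inherits(frames, "frame_sequence"))
    if (!identical(as.integer(frames$day_index), as.integer(curve$days)))
      stop("frame sequence day axis does not match the curve", call. = FALSE)
  }
  coords <- NULL
  if (!is.null(trajectories)) {
    stopifnot(inherits(trajectories, "worm_trajectories"))
    nd <- dim(trajectories$positions)[3]
    if (nd != length(curve$days))
      stop("trajectory day axis does not match the curve", call. = FALSE)
    coords <- lapply(seq_len(nd), function(d)
      matrix(trajectories$positions[, , d], ncol = 2L))
  }
  fd <- first_drop_day(curve)
  last_day <- max(curve$days)
  ks <- seq.int(fd, last_day - 1L)
  lapply(ks, function(k) {
    structure(list(
      count_prefix = curve$live_counts[seq_len(k + 1L)],
      frame_prefix = if (is.null(frames)) NULL else frames$frames[seq_len(k + 1L)],
      coord_prefix = if (is.null(coords)) NULL else coords[seq_len(k + 1L)],
      label = curve$live_counts[(k + 2L):(last_day + 1L)],
      k = k,
      initial_count = curve$initial_count,
      plate_id = curve$plate_id), class = "model_sample")
  })
}

#' Sampling law for simulator parameters
#'
#' Defaults cover the design range of the method: plates of 10--15 worms with
#' mean lifespans between 10 and 57 days; the Weibull shape range 3--10 spans
#' shallow to fairly sharp mortality curves.
#'
#' @param a_range,b_range Numeric `c(min, max)` for uniform draws of the
#'   Weibull shape and scale.
#' @param n_range Integer `c(min, max)` for uniform draws of worms per plate.
#' @param gap_spec A [gap_spec()] applied to every curve (with its own
#'   application probability), or `NULL` for clean curves.
#' @return An object of class `param_law`.
#' @export
param_law <- function(a_range = c(3, 10), b_range = c(10, 57),
                      n_range = c(10L, 15L), gap_spec = wormcast::gap_spec()) {
  stopifnot(length(a_range) == 2L, length(b_range) == 2L,
            length(n_range) == 2L, a_range[1] > 0, b_range[1] > 0)
  structure(list(a_range = a_range, b_range = b_range,
                 n_range = as.integer(n_range), gap_spec = gap_spec),
            class = "param_law")
}

draw_params <- function(law, max_days) {
  a <- stats::runif(1, law$a_range[1], law$a_range[2])
  b <- stats::runif(1, law$b_range[1], law$b_range[2])
  n <- sample(law$n_range[1]:law$n_range[2], 1L)
  # simulate with a horizon comfortably past extinction; the label horizon
  # is enforced by rejection in build_dataset
  suppressWarnings(simulator_params(n, a, b,
                                    max_days = max(max_days,
                                                   ceiling(2.5 * b)),
                                    gap_spec = law$gap_spec))
}

#' Train/validation split settings
#'
#' The split unit is the curve: all samples cut from one curve share its
#' split, because samples from the same curve are near-duplicates and a
#' sample-level split would leak information from training into validation.
#'
#' @param train_fraction Fraction of curves assigned to training
#'   (default 0.8).
#' @return An object of class `dataset_split`.
#' @export
dataset_split <- function(train_fraction = 0.8) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(train_fraction = train_fraction, split_unit = "curve"),
            class = "dataset_split")
}

#' Build a simulated training dataset
#'
#' Runs the full simulation chain per curve -- [generate_curve()],
#' [apply_capture_gaps()], [sample_trajectories()], [render_sequence()],
#' [make_samples()] -- and splits the resulting samples by curve.
#'
#' @param n_curves Number of plates to simulate (`>= 2`).
#' @param law A [param_law()].
#' @param split A [dataset_split()].
#' @param seed RNG seed; the whole dataset is reproducible from it.
#' @param image_spec An [image_spec()]; also fixes the arena size.
#' @param arena_radius_frac Food-lawn radius fraction passed to
#'   [arena_spec()].
#' @param max_days Label horizon in days (default 60); curves are simulated
#'   with a wider internal horizon so they can extinguish, then samples are
#'   restricted to curves extinct within `max_days`.
#' @param render Set `FALSE` to skip image rendering (count-only datasets,
#'   much faster).
#' @return An object of class `worm_dataset`: list with `samples` (list of
#'   `model_sample`), `split` (character vector `"train"`/`"val"` per
#'   sample), `manifest` (per-curve data frame), `max_days`, `image_spec`.
#' @export
build_dataset <- function(n_curves, law = param_law(),
                          split = dataset_split(), seed = NULL,
                          image_spec = wormcast::image_spec(),
                          arena_radius_frac = 0.7, max_days = 60L,
                          render = TRUE) {
  n_curves <- as.integer(n_curves)
  if (n_curves < 2L) stop("need at least 2 curves to split", call. = FALSE)
  if (law$b_range[2] > max_days)
    stop("param_law b_range exceeds the label horizon max_days", call. = FALSE)
  arena <- arena_spec(side = image_spec$side, radius_frac = arena_radius_frac)
  with_seed(seed, {
    samples <- list(); sample_curve <- integer(0)
    man <- vector("list", n_curves)
    for (i in seq_len(n_curves)) {
      repeat {
        params <- draw_params(law, max_days = max_days)
        params$seed <- NULL
        plate <- simulate_plate(params, arena = arena)
        plate$curve$plate_id <- sprintf("c%04d", i)
        plate$trajectories$plate_id <- plate$curve$plate_id
        # keep only curves extinct within the label horizon and with at
        # least one predictable day
        if (max(plate$curve$days) <= max_days &&
            max(plate$curve$days) - first_drop_day(plate$curve) >= 1L) break
      }
      fs <- if (render) render_sequence(plate$trajectories, image_spec) else NULL
      cs <- make_samples(plate$curve, fs, plate$trajectories)
      samples <- c(samples, cs)
      sample_curve <- c(sample_curve, rep(i, length(cs)))
      man[[i]] <- data.frame(
        curve_id = plate$curve$plate_id, a = params$a, b = params$b,
        n_worms = params$n_worms,
        first_drop_day = first_drop_day(plate$curve),
        last_day = max(plate$curve$days), n_samples = length(cs))
    }
    manifest <- do.call(rbind, man)
    n_train <- max(1L, round(split$train_fraction * n_curves))
    train_curves <- sample(n_curves, n_train)
    manifest$split <- ifelse(seq_len(n_curves) %in% train_curves,
                             "train", "val")
    structure(list(samples = samples,
                   sample_curve = sample_curve,
                   split = manifest$split[sample_curve],
                   manifest = manifest,
                   max_days = as.integer(max_days),
                   image_spec = image_spec),
              class = "worm_dataset")
  })
}

#' @export
print.worm_dataset <- function(x, ...) {
  cat("<worm_dataset> ", nrow(x$manifest), " curves, ", length(x$samples),
      " samples (", sum(x$split == "train"), " train / ",
      sum(x$split == "val"), " val), horizon ", x$max_days, " days\n",
      sep = "")
  invisible(x)
}

#' Extract the train or validation samples of a dataset
#'
#' @param dataset A `worm_dataset`.
#' @param which `"train"` or `"val"`.
#' @return List of `model_sample`.
#' @export
dataset_samples <- function(dataset, which = c("train", "val")) {
  which <- match.arg(which)
  dataset$samples[dataset$split == which]
}
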
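#' Weibull survival function
#'
#' Survival fraction of a population whose individual lifetimes follow a
#' 2-parameter Weibull law, `S(t) = exp(-(t/b)^a)`. The shape `a` controls the
#' steepness of the mortality curve (large `a` concentrates deaths around
#' `t = b`); the scale `b` is close to the mean lifespan (the exact mean is
#' `b * gamma(1 + 1/a)`, which tends to `b` as `a` grows).
#'
#' @param t Time in days (vectorised), `t >= 0`.
#' @param a Weibull shape, `> 0` (dimensionless).
#' @param b Weibull scale, `> 0` (days).
#' @return Survival fraction(s) in `[0, 1]`; 1 at `t = 0`, strictly
#'   decreasing for `t > 0`.
#' @examples
#' weibull_survival(0, 5, 14)            # 1
#' weibull_survival(14, 5, 14)           # exp(-1)
#' weibull_survival(0:30, a = 5, b = 20)
#' @export
weibull_survival <- function(t, a, b) {
  if (any(a <= 0) || any(b <= 0))
    stop("Weibull parameters must be positive: a > 0, b > 0", call. = FALSE)
  if (any(t < 0))
    stop("time 't' must be non-negative", call. = FALSE)
  exp(-(t / b)^a)
}

#' Capture-gap distortion settings
#'
#' Lifespan assays that rely on an operator to place plates in the imaging rig
#' have days with no capture (typically weekends); on those days the count of
#' the last captured day is carried forward, producing steps in the curve.
#' This object describes where those gaps fall.
#'
#' @param gap_len Number of consecutive gap days per period (default 2,
#'   weekend-style).
#' @param period Period in days between gap blocks (default 7).
#' @param phase Offset in days of the first gap block within the period, or
#'   `NULL` to draw it uniformly at random when the gaps are applied.
#' @param prob Probability that a given curve receives gaps at all
#'   (default 0.5).
#' @return An object of class `gap_spec`.
#' @export
gap_spec <- function(gap_len = 2L, period = 7L, phase = NULL, prob = 0.5) {
  gap_len <- as.integer(gap_len); period <- as.integer(period)
  stopifnot(gap_len >= 0L, period >= 1L, prob >= 0, prob <= 1)
  if (gap_len >= period)
    stop("gap_len must be smaller than the period", call. = FALSE)
  if (!is.null(phase)) {
    phase <- as.integer(phase)
    stopifnot(phase >= 0L, phase < period)
  }
  structure(list(gap_len = gap_len, period = period, phase = phase,
                 prob = prob),
            class = "gap_spec")
}

#' Simulator parameters for one plate
#'
#' @param n_worms Number of worms on the plate. The supported design range is
#'   10--16 (values outside it are accepted with a warning).
#' @param a Weibull shape (slope of the mortality curve), `> 0`.
#' @param b Weibull scale (approximately the mean lifespan, days), `> 0`. The
#'   supported design range is 10--57 days.
#' @param max_days Horizon in days; must be at least `ceiling(b)` so that the
#'   curve can reach zero. Default `max(60, ceiling(2.5 * b))`.
#' @param gap_spec A [gap_spec()] describing capture-gap distortions, or
#'   `NULL` for none.
#' @param seed RNG seed for reproducible generation, or `NULL`.
#' @return An object of class `simulator_params`.
#' @seealso [generate_curve()], [simulate_plate()]
#' @export
simulator_params <- function(n_worms, a, b,
                             max_days = max(60L, ceiling(2.5 * b)),
                             gap_spec = NULL, seed = NULL) {
  n_worms <- as.integer(n_worms)
  if (n_worms < 1L) stop("n_worms must be >= 1", call. = FALSE)
  if (a <= 0 || b <= 0)
    stop("Weibull parameters must be positive: a > 0, b > 0", call. = FALSE)
  if (n_worms < 10L || n_worms > 16L)
    warning("n_worms outside the supported design range [10, 16]")
  if (b < 10 || b > 57)
    warning("mean-lifespan scale b outside the supported design range [10, 57]")
  max_days <- as.integer(max_days)
  if (max_days < ceiling(b))
    stop("max_days too small: the curve cannot reach zero before the horizon",
         call. = FALSE)
  if (!is.null(gap_spec) && !inherits(gap_spec, "gap_spec"))
    stop("gap_spec must be created with gap_spec()", call. = FALSE)
  structure(list(n_worms = n_worms, a = a, b = b, max_days = max_days,
                 gap_spec = gap_spec, seed = seed),
            class = "simulator_params")
}

#' Construct a lifespan curve
#'
#' A lifespan curve is the per-day number of live worms on one plate, from the
#' first capture day (day 0, all worms alive) to extinction.
#'
#' @param live_counts Integer vector of live counts, one per day starting at
#'   day 0; must be non-increasing and end at 0.
#' @param plate_id Optional identifier carried through to outputs.
#' @return An object of class `lifespan_curve` with fields `days`
#'   (0-based integer day index), `live_counts` and `initial_count`.
#' @export
lifespan_curve <- function(live_counts, plate_id = NA_character_) {
  live_counts <- as.integer(live_counts)
  if (length(live_counts) < 1L) stop("empty curve", call. = FALSE)
  if (any(diff(live_counts) > 0L))
    stop("live counts must be non-increasing", call. = FALSE)
  if (any(live_counts < 0L)) stop("negative live count", call. = FALSE)
  structure(list(days = seq_along(live_counts) - 1L,
                 live_counts = live_counts,
                 initial_count = live_counts[1L],
                 plate_id = plate_id),
            class = "lifespan_curve")
}

#' @export
print.lifespan_curve <- function(x, ...) {
  cat("<lifespan_curve> ", x$initial_count, " worms, ",
      length(x$days), " days (0..", max(x$days), ")\n", sep = "")
  cat("  counts:", paste(x$live_counts, collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.lifespan_curve <- function(x, ...) {
  data.frame(plate_id = x$plate_id, day = x$days, live_count = x$live_counts,
             initial_count = x$initial_count)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Draw worm lifetimes from a Weibull truncated at max_days. The truncation is
# a horizon device, not part of the mortality model: with the recommended
# horizons (max_days >= 2.5 b) the truncated mass is negligible.
draw_lifetimes <- function(n, a, b, max_days) {
  lt <- stats::rweibull(n, shape = a, scale = b)
  for (i in 1:100) {
    over <- lt > max_days
    if (!any(over)) break
    lt[over] <- stats::rweibull(sum(over), shape = a, scale = b)
  }
  pmin(lt, max_days)
}

#' Generate a lifespan curve from the Weibull model
#'
#' Realises one plate's daily live counts. Under the default stochastic
#' discretisation each worm draws an independent continuous Weibull lifetime
#' and dies on day `ceiling(lifetime)`; the expected per-day survival equals
#' [weibull_survival()]. The deterministic alternative rounds
#' `n_worms * S(t)` day by day, giving the idealised (noise-free) curve.
#'
#' @param params A [simulator_params()] object.
#' @param method `"stochastic"` (default) or `"deterministic"`.
#' @return A [lifespan_curve()] ending at 0, reproducible given
#'   `params$seed`.
#' @export
generate_curve <- function(params, method = c("stochastic", "deterministic")) {
  stopifnot(inherits(params, "simulator_params"))
  method <- match.arg(method)
  n <- params$n_worms
  if (method == "deterministic") {
    s <- weibull_survival(0:params$max_days, params$a, params$b)
    counts <- round(n * s)
    counts[1L] <- n
    counts <- cummin(as.integer(counts))
  } else {
    counts <- with_seed(params$seed, {
      lt <- draw_lifetimes(n, params$a, params$b, params$max_days)
      death_day <- pmax(1L, as.integer(ceiling(lt)))
      vapply(0:params$max_days, function(d) sum(death_day > d), integer(1))
    })
  }
  if (counts[length(counts)] != 0L)
    stop("curve did not reach zero within max_days (horizon error)",
         call. = FALSE)
  ext <- which(counts == 0L)[1L]
  lifespan_curve(counts[seq_len(ext)])
}

# Days (0-based) on which no capture happens for a given phase.
gap_days_for <- function(spec, n_days, phase) {
  if (spec$gap_len == 0L) return(integer(0))
  d <- 1:(n_days - 1L)                      # day 0 is always captured
  d[((d - phase) %% spec$period) < spec$gap_len]
}

#' Apply capture-gap distortions to a curve
#'
#' On each gap (no-capture) day the count of the last captured day is carried
#' forward, producing the step pattern seen in operator-captured assays. Day 0
#' is never a gap, monotonicity is preserved, and the curve's end value is
#' unchanged (deaths are caught up on the next captured day). If a gap block
#' covers the extinction day the curve is extended to the next captured day,
#' where the 0 count is finally observed.
#'
#' @param curve A [lifespan_curve()].
#' @param spec A [gap_spec()]. With `phase = NULL` the phase is drawn
#'   uniformly from `0:(period-1)` using the current RNG stream; the
#'   per-curve application probability `prob` is also resolved here.
#' @return A [lifespan_curve()] with held counts on gap days.
#' @export
apply_capture_gaps <- function(curve, spec) {
  stopifnot(inherits(curve, "lifespan_curve"), inherits(spec, "gap_spec"))
  n_days <- length(curve$live_counts)
  if (spec$gap_len >= n_days)
    stop("gap length must be shorter than the curve", call. = FALSE)
  if (spec$gap_len == 0L || stats::runif(1) > spec$prob) return(curve)
  phase <- if (is.null(spec$phase)) sample.int(spec$period, 1L) - 1L else spec$phase
  # pad with the post-extinction zeros so a gap on the extinction day resolves
  # at the next captured day instead of truncating the curve
  counts <- c(curve$live_counts, rep(0L, spec$period))
  gaps <- gap_days_for(spec, length(counts), phase)
  for (d in gaps) counts[d + 1L] <- counts[d]      # hold last captured value
  counts <- counts[seq_len(which(counts == 0L)[1L])]
  out <- lifespan_curve(counts, plate_id = curve$plate_id)
  attr(out, "gap_days") <- gaps[gaps < length(counts) - 1L]
  out
}

#' Arena geometry for worm positions
#'
#' Worms are positioned inside a central disc emulating the bacterial food
#' lawn placed at the centre of the plate (which also keeps them away from the
#' image borders).
#'
#' @param side Image side length in pixels the positions are expressed in.
#' @param radius_frac Lawn radius as a fraction of `side / 2` (default 0.7).
#' @return An object of class `arena_spec`.
#' @export
arena_spec <- function(side = 64L, radius_frac = 0.7) {
  side <- as.integer(side)
  stopifnot(side >= 4L, radius_frac > 0, radius_frac <= 1)
  structure(list(side = side, radius_frac = radius_frac), class = "arena_spec")
}

# n uniform positions in the central food-lawn disc; matrix [n, 2] = (x, y).
runif_disc <- function(n, arena) {
  r <- arena$radius_frac * arena$side / 2 * sqrt(stats::runif(n))
  th <- 2 * pi * stats::runif(n)
  centre <- (arena$side - 1) / 2
  cbind(x = centre + r * cos(th), y = centre + r * sin(th))
}

#' Sample per-worm trajectories consistent with a lifespan curve
#'
#' Worm deaths are assigned from the day-to-day drops of the curve (worms are
#' exchangeable, so the dying worms each day are picked at random among the
#' living). A live worm takes a fresh uniform position inside the food-lawn
#' disc every day; once dead it keeps the position it died at -- position
#' change between days is precisely the movement signal the image branch of
#' the model exploits.
#'
#' @param curve A [lifespan_curve()].
#' @param arena An [arena_spec()].
#' @param seed Optional RNG seed.
#' @return An object of class `worm_trajectories`: a list with `positions`
#'   (array `[n_worms, 2, n_days]` of (x, y) pixel coordinates), `death_day`
#'   (integer day index of death, or `NA` if the worm survives to the end of
#'   the curve -- impossible for extinct curves), and `alive_mask`
#'   (`[n_worms, n_days]` logical).
#' @export
sample_trajectories <- function(curve, arena = arena_spec(), seed = NULL) {
  stopifnot(inherits(curve, "lifespan_curve"), inherits(arena, "arena_spec"))
  counts <- curve$live_counts
  n <- curve$initial_count
  n_days <- length(counts)
  with_seed(seed, {
    death_day <- rep(NA_integer_, n)
    alive <- seq_len(n)
    for (d in seq_len(n_days - 1L)) {            # transitions into day d
      k <- counts[d] - counts[d + 1L]
      if (k > 0L) {
        dying <- if (length(alive) == 1L) alive else sample(alive, k)
        death_day[dying] <- d
        alive <- setdiff(alive, dying)
      }
    }
    pos <- array(NA_real_, dim = c(n, 2L, n_days))
    for (d in seq_len(n_days)) {
      day <- d - 1L
      # a worm found dead on its death day lies where it was last seen alive
      moving <- which(is.na(death_day) | death_day > day)
      if (length(moving) > 0L)
        pos[moving, , d] <- runif_disc(length(moving), arena)
      frozen <- which(!is.na(death_day) & death_day <= day)
      if (length(frozen) > 0L)
        pos[frozen, , d] <- pos[frozen, , d - 1L]
    }
    amask <- outer(seq_len(n), 0:(n_days - 1L),
                   function(w, d) is.na(death_day[w]) | death_day[w] > d)
    structure(list(positions = pos, death_day = death_day,
                   alive_mask = amask, arena = arena,
                   plate_id = curve$plate_id),
              class = "worm_trajectories")
  })
}

#' @export
as.data.frame.worm_trajectories <- function(x, ...) {
  n <- dim(x$positions)[1]; n_days <- dim(x$positions)[3]
  data.frame(
    plate_id = x$plate_id,
    worm_id = rep(seq_len(n), times = n_days),
    day = rep(0:(n_days - 1L), each = n),
    x = as.vector(x$positions[, 1, ]),
    y = as.vector(x$positions[, 2, ]),
    alive = as.vector(x$alive_mask))
}

#' Simulate one complete plate
#'
#' Convenience wrapper running [generate_curve()], [apply_capture_gaps()]
#' (when `params$gap_spec` is set) and [sample_trajectories()] under a single
#' seeded RNG stream.
#'
#' @param params A [simulator_params()].
#' @param arena An [arena_spec()].
#' @param method Discretisation passed to [generate_curve()].
#' @return List with elements `curve` (gapped, the observed curve) and
#'   `trajectories`.
#' @export
simulate_plate <- function(params, arena = arena_spec(),
                           method = "stochastic") {
  with_seed(params$seed, {
    p2 <- params; p2$seed <- NULL                 # already inside the stream
    curve <- generate_curve(p2, method = method)
    if (!is.null(params$gap_spec))
      curve <- apply_capture_gaps(curve, params$gap_spec)
    traj <- sample_trajectories(curve, arena = arena)
    list(curve = curve, trajectories = traj)
  })
}
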
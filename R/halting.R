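#' Reconstruct death events from a count curve
#'
#' Deaths on day `d` are the drop `count(d-1) - count(d)`; worms still alive
#' on the last day of the curve are right-censored there.
#'
#' @param curve A [lifespan_curve()] or a non-increasing integer vector of
#'   live counts (day 0 first).
#' @return A data frame with columns `day` and `deaths` (only days with at
#'   least one death), with attributes `initial` (starting count) and
#'   `censored` (survivors at the last day).
#' @export
curve_to_events <- function(curve) {
  counts <- if (inherits(curve, "lifespan_curve")) curve$live_counts
            else as.numeric(curve)
  if (any(diff(counts) > 0))
    stop("live counts must be non-increasing (monotonicity error)",
         call. = FALSE)
  drops <- -diff(counts)
  days <- seq_along(drops)                         # 0-based day of the drop
  ev <- data.frame(day = days[drops > 0], deaths = drops[drops > 0])
  attr(ev, "initial") <- counts[1L]
  attr(ev, "censored") <- counts[length(counts)]
  ev
}

#' Log-rank (Mantel--Cox) test between two count curves
#'
#' Standard unweighted log-rank test comparing the survival experiences
#' encoded by two daily live-count curves sharing day 0 as origin. At each
#' distinct death day `j` the observed group-1 deaths `d1j` are compared
#' with their hypergeometric expectation `e1j = dj * n1j / nj` under the
#' null of a common hazard; the statistic `(sum(d1j - e1j))^2 / sum(vj)`
#' with the hypergeometric variances `vj` is referred to a chi-square
#' distribution with 1 degree of freedom. Worms alive at the end of either
#' curve are right-censored there. Identical curves give statistic 0 and
#' p = 1.
#'
#' @param curveA,curveB [lifespan_curve()]s or non-increasing count vectors.
#' @return List with `statistic` (chi-square), `p_value`, and the per-event
#'   `table` (day, n1, n2, d1, d2, e1, v).
#' @export
logrank_test <- function(curveA, curveB) {
  ca <- if (inherits(curveA, "lifespan_curve")) curveA$live_counts else as.numeric(curveA)
  cb <- if (inherits(curveB, "lifespan_curve")) curveB$live_counts else as.numeric(curveB)
  if (any(diff(ca) > 0) || any(diff(cb) > 0))
    stop("live counts must be non-increasing", call. = FALSE)
  evA <- curve_to_events(ca); evB <- curve_to_events(cb)
  if (nrow(evA) == 0L && nrow(evB) == 0L)
    stop("no death events in either curve (undefined test)", call. = FALSE)
  days <- sort(union(evA$day, evB$day))
  at_risk <- function(counts, d) if (d <= length(counts) - 1L) counts[d] else 0
  deaths_on <- function(ev, d) {
    i <- match(d, ev$day); if (is.na(i)) 0 else ev$deaths[i]
  }
  tab <- do.call(rbind, lapply(days, function(d) {
    n1 <- at_risk(ca, d); n2 <- at_risk(cb, d)
    d1 <- deaths_on(evA, d); d2 <- deaths_on(evB, d)
    nj <- n1 + n2; dj <- d1 + d2
    e1 <- dj * n1 / nj
    v <- if (nj > 1) dj * (n1 / nj) * (n2 / nj) * (nj - dj) / (nj - 1) else 0
    data.frame(day = d, n1 = n1, n2 = n2, d1 = d1, d2 = d2, e1 = e1, v = v)
  }))
  OmE <- sum(tab$d1 - tab$e1); V <- sum(tab$v)
  if (V <= 0) {
    # only possible when every comparison is degenerate, i.e. O - E = 0
    stat <- 0; p <- 1
  } else {
    stat <- OmE^2 / V
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(statistic = stat, p_value = p, table = tab)
}

# Round half-up to integers and restore monotonicity from the observed
# prefix; the log-rank test needs integral, non-increasing event counts.
integerise_bound <- function(future, last_obs) {
  as.integer(cummin(c(last_obs, floor(future + 0.5)))[-1L])
}

#' Halting verdict for one condition band
#'
#' Builds the two survival curves traced by the lower and upper confidence
#' bounds (both starting from the condition's observed prefix, rounded
#' half-up and re-monotonised), runs the log-rank test between them, and
#' declares the prediction reliable -- i.e. the assay may halt -- when the
#' bounds do not differ significantly (`p > alpha`).
#'
#' @param band A `condition_band` from [propagate_condition()].
#' @param alpha Significance level; defaults to the band's.
#' @return List with `halt` (logical), `p_value`, `statistic`,
#'   `lower_curve`, `upper_curve` (full integer curves from day 0).
#' @export
halt_decision <- function(band, alpha = band$alpha) {
  stopifnot(inherits(band, "condition_band"))
  obs <- as.integer(round(band$obs_prefix))
  last_obs <- obs[length(obs)]
  lower <- c(obs, integerise_bound(band$ci_lower, last_obs))
  upper <- c(obs, integerise_bound(band$ci_upper, last_obs))
  if (identical(lower, upper))
    return(list(halt = TRUE, p_value = 1, statistic = 0,
                lower_curve = lower, upper_curve = upper))
  lr <- logrank_test(lower, upper)
  list(halt = lr$p_value > alpha, p_value = lr$p_value,
       statistic = lr$statistic, lower_curve = lower, upper_curve = upper)
}

#' Scan the assay for the first reliable halting day
#'
#' Replays the assay day by day: for each current day `k` (starting at the
#' first day the curve has fallen in every plate of the condition -- before
#' that, plate-level uncertainty is unfounded) it predicts every plate with
#' Monte-Carlo uncertainty, propagates to the condition band, and applies
#' the log-rank halting criterion. The proposed halting day is the first
#' `k` whose bounds do not differ significantly.
#'
#' @param predictor A trained `worm_predictor`.
#' @param plates List of plates; each element is a list with `curve` (a
#'   complete [lifespan_curve()]) and, for image/coordinate modes, `frames`
#'   (a `frame_sequence`) and/or `trajectories`.
#' @param noise A [noise_spec()].
#' @param alpha Significance level of the band and the test (default 0.05).
#' @param sqrt_n Passed to [propagate_condition()].
#' @param max_day Last day to evaluate; default the condition's extinction
#'   day minus 1.
#' @return An object of class `halt_report`: list with `halt_day` (integer
#'   or `NA` if no day qualifies), `trace` (data frame `day`, `p_value`,
#'   `statistic`, `halt`), `start_day`, `alpha`, and `band` (the condition
#'   band at the halting day, or the last evaluated band).
#' @export
find_halt_day <- function(predictor, plates, noise = noise_spec(),
                          alpha = 0.05, sqrt_n = TRUE, max_day = NULL) {
  stopifnot(length(plates) >= 1L)
  cfg <- predictor$config
  curves <- lapply(plates, `[[`, "curve")
  start_day <- max(vapply(curves, first_drop_day, integer(1)))
  ext_day <- max(vapply(curves, function(cu) max(cu$days), integer(1)))
  if (is.null(max_day)) max_day <- ext_day - 1L
  max_day <- min(max_day, cfg$max_days - 1L)
  if (start_day > max_day)
    stop("no qualifying start day: curves must fall in all plates before ",
         "the evaluation horizon (not-started error)", call. = FALSE)
  trace <- data.frame(day = integer(0), p_value = numeric(0),
                      statistic = numeric(0), halt = logical(0))
  halt_day <- NA_integer_; band_out <- NULL
  for (k in start_day:max_day) {
    preds <- lapply(seq_along(plates), function(i) {
      pl <- plates[[i]]
      cu <- pl$curve
      counts <- observed_counts(cu, k)
      fp <- if (uses_images(cfg)) observed_frames(pl$frames, k) else NULL
      cp <- if (uses_coords(cfg) || noise$target == "positions")
        observed_coords(pl, k) else NULL
      # error propagation assumes independent plates: give each its own
      # noise stream
      pn <- noise
      if (!is.null(pn$seed)) pn$seed <- pn$seed + (i - 1L) * 100003L
      estimate_plate(predictor, counts, fp, pn, coord_prefix = cp,
                     initial_count = cu$initial_count)
    })
    band <- propagate_condition(preds, alpha = alpha, sqrt_n = sqrt_n)
    dec <- halt_decision(band, alpha = alpha)
    trace <- rbind(trace, data.frame(day = k, p_value = dec$p_value,
                                     statistic = dec$statistic,
                                     halt = dec$halt))
    band_out <- band
    if (dec$halt) { halt_day <- k; break }
  }
  structure(list(halt_day = halt_day, trace = trace, start_day = start_day,
                 alpha = alpha, band = band_out),
            class = "halt_report")
}

#' @export
print.halt_report <- function(x, ...) {
  if (is.na(x$halt_day))
    cat("<halt_report> no qualifying halting day (", nrow(x$trace),
        " days evaluated)\n", sep = "")
  else
    cat("<halt_report> halt proposed at day ", x$halt_day, " (p = ",
        signif(x$trace$p_value[nrow(x$trace)], 3), ")\n", sep = "")
  invisible(x)
}

# Observed live counts of a plate at current day k: the curve, extended with
# zeros if the plate is already extinct.
observed_counts <- function(curve, k) {
  counts <- curve$live_counts
  if (length(counts) < k + 1L)
    counts <- c(counts, rep(0L, k + 1L - length(counts)))
  counts[seq_len(k + 1L)]
}

# Frames up to day k; after extinction every worm is frozen, so the last
# frame simply repeats.
observed_frames <- function(frames, k) {
  stopifnot(inherits(frames, "frame_sequence"))
  fr <- frames$frames
  if (length(fr) < k + 1L)
    fr <- c(fr, rep(fr[length(fr)], k + 1L - length(fr)))
  fr[seq_len(k + 1L)]
}

observed_coords <- function(pl, k) {
  tr <- pl$trajectories
  if (is.null(tr)) return(NULL)
  nd <- dim(tr$positions)[3]
  cp <- lapply(seq_len(min(nd, k + 1L)), function(d)
    matrix(tr$positions[, , d], ncol = 2L))
  if (length(cp) < k + 1L)
    cp <- c(cp, rep(cp[length(cp)], k + 1L - length(cp)))
  cp
}
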
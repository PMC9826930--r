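#' Survival percentage
#'
#' @param count Live count (worms), `>= 0`; vectorised.
#' @param initial Initial live count (worms), `> 0`.
#' @return `count * 100 / initial`.
#' @export
percent_live <- function(count, initial) {
  if (any(initial <= 0)) stop("initial count must be > 0", call. = FALSE)
  if (any(count < 0)) stop("count must be >= 0", call. = FALSE)
  count * 100 / initial
}

#' Mean absolute error between survival curves, in percentage points
#'
#' Both curves are converted to survival percentages and the absolute
#' differences are averaged day by day over the supplied (aligned) range --
#' in practice the future period, from the day the assay stops to the end;
#' the earlier period is known and excluded.
#'
#' @param reference,predicted Aligned live-count vectors over the evaluation
#'   day range (same length, `>= 1`).
#' @param initial_reference Initial count normalising the reference curve;
#'   default 100 (i.e. inputs already in percent).
#' @param initial_predicted Initial count normalising the predicted curve;
#'   defaults to `initial_reference`.
#' @return MAE in percentage points of survival.
#' @export
mae_percent <- function(reference, predicted, initial_reference = 100,
                        initial_predicted = initial_reference) {
  if (length(reference) == 0L)
    stop("empty evaluation day range", call. = FALSE)
  if (length(reference) != length(predicted))
    stop("curves are not aligned over the evaluation range", call. = FALSE)
  mean(abs(percent_live(reference, initial_reference) -
             percent_live(predicted, initial_predicted)))
}

#' Mean lifespan of a count curve
#'
#' The average death day of the population, with deaths reconstructed from
#' the day-to-day drops of the curve (a drop of `m` at day `d` contributes
#' `m` deaths at day `d`). For a curve that has not reached zero the
#' survivors are counted at the last observed day and a restricted-mean
#' warning is raised.
#'
#' @param curve A [lifespan_curve()] or non-increasing count vector.
#' @return Mean lifespan in days.
#' @export
mean_lifespan <- function(curve) {
  counts <- if (inherits(curve, "lifespan_curve")) curve$live_counts
            else as.numeric(curve)
  ev <- curve_to_events(counts)
  initial <- attr(ev, "initial")
  if (initial <= 0) stop("empty plate", call. = FALSE)
  censored <- attr(ev, "censored")
  total <- sum(ev$deaths * ev$day)
  if (censored > 0) {
    warning("curve not extinct: returning the restricted mean lifespan")
    total <- total + censored * (length(counts) - 1L)
  }
  total / initial
}

#' Weibull curve-fit baseline
#'
#' The classical alternative to a learned predictor: fit
#' `count(t) = initial * exp(-(t/b)^a)` to the observed prefix by
#' Levenberg--Marquardt nonlinear least squares and extrapolate it over the
#' remaining horizon.
#'
#' @param count_prefix Observed live counts for days `0..k` (at least two
#'   distinct values; a flat prefix cannot identify the parameters).
#' @param initial Initial live count; defaults to `count_prefix[1]`.
#' @param horizon Last day of the extrapolated curve.
#' @param a_init,b_init Starting values; `b_init` defaults to the last
#'   observed day with more than 50% survival (or the prefix midpoint).
#' @return List with `a`, `b`, `fitted` (counts for days `0..horizon`) and
#'   `future` (counts for days `k+1..horizon`).
#' @export
weibull_fit_baseline <- function(count_prefix, initial = count_prefix[1L],
                                 horizon, a_init = 5, b_init = NULL) {
  y <- as.numeric(count_prefix)
  if (length(unique(y)) < 2L)
    stop("degenerate prefix: no decline to fit (fit-failure error)",
         call. = FALSE)
  t <- seq_along(y) - 1
  if (is.null(b_init)) {
    over <- which(y > initial / 2)
    b_init <- if (length(over) > 0L) max(t[over], 1) else max(t) / 2
  }
  df <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ initial * exp(-(t / b)^a), data = df,
                      start = list(a = a_init, b = b_init),
                      lower = c(a = 0.5, b = 1), upper = c(a = 100, b = 200),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("Weibull fit failed: ", conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  tt <- 0:horizon
  fitted <- initial * exp(-(tt / cf[["b"]])^cf[["a"]])
  k <- length(y) - 1L
  future <- if (horizon > k) fitted[(k + 2L):(horizon + 1L)] else numeric(0)
  list(a = cf[["a"]], b = cf[["b"]], fitted = fitted, future = future)
}

# Condition-level reference curve: summed plate counts, shorter plates
# extended with zeros past their extinction.
condition_reference <- function(curves) {
  L <- max(vapply(curves, function(cu) length(cu$live_counts), integer(1)))
  counts <- Reduce(`+`, lapply(curves, function(cu)
    c(cu$live_counts, rep(0L, L - length(cu$live_counts)))))
  lifespan_curve(counts, plate_id = "condition")
}

#' Evaluate the full prediction pipeline on one condition
#'
#' Replays the condition with [find_halt_day()]; at the proposed halting day
#' it assembles the predicted condition curve (observed prefix + rounded
#' mean predicted suffix) and scores it against the reference: MAE in
#' survival percentage points over the future period, mean lifespans,
#' log-rank p-value between reference and prediction, and the same MAE for
#' the Weibull curve-fit baseline extrapolated from the identical prefix.
#'
#' @param predictor A trained `worm_predictor` (or [oracle_predictor()]).
#' @param plates Condition plates as for [find_halt_day()]; their curves are
#'   the complete references.
#' @param noise A [noise_spec()].
#' @param alpha Significance level (default 0.05).
#' @param sqrt_n Passed to [propagate_condition()].
#' @return An object of class `evaluation_report`: list with `summary` (one
#'   row: `mean_lifespan_ref`, `mean_lifespan_pred`, `halt_day`,
#'   `mae_percent`, `p_value`, `baseline_mae_percent`, `baseline_a`,
#'   `baseline_b`), plus `halt_report`, `reference`, `predicted_curve`,
#'   `baseline_curve`, and `eval_days`.
#' @export
evaluate_assay <- function(predictor, plates, noise = noise_spec(),
                           alpha = 0.05, sqrt_n = TRUE) {
  curves <- lapply(plates, `[[`, "curve")
  ref <- condition_reference(curves)
  hr <- find_halt_day(predictor, plates, noise = noise, alpha = alpha,
                      sqrt_n = sqrt_n)
  k <- if (is.na(hr$halt_day)) hr$trace$day[nrow(hr$trace)] else hr$halt_day
  band <- hr$band
  total_initial <- band$total_initial
  # predicted condition curve: observed prefix + rounded mean suffix
  obs <- as.integer(round(band$obs_prefix))
  pred_suffix <- integerise_bound(band$mean_curve, obs[length(obs)])
  pred_curve <- c(obs, pred_suffix)
  max_day_model <- predictor$config$max_days
  ref_ext <- max(ref$days)
  eval_days <- (k + 1L):min(ref_ext, max_day_model)
  ref_full <- c(ref$live_counts, rep(0L, max(0L, max_day_model + 1L -
                                               length(ref$live_counts))))
  mae_nn <- mae_percent(ref_full[eval_days + 1L], pred_curve[eval_days + 1L],
                        initial_reference = total_initial)
  # Weibull curve-fit baseline from the same observed prefix
  base <- tryCatch(
    weibull_fit_baseline(obs, initial = total_initial,
                         horizon = max(eval_days)),
    error = function(e) NULL)
  mae_base <- if (is.null(base)) NA_real_ else
    mae_percent(ref_full[eval_days + 1L],
                base$fitted[eval_days + 1L],
                initial_reference = total_initial)
  ml_ref <- mean_lifespan(ref)
  ml_pred <- suppressWarnings(mean_lifespan(pred_curve))
  p_ref_pred <- logrank_test(ref_full[seq_len(max(eval_days) + 1L)],
                             pred_curve[seq_len(max(eval_days) + 1L)])$p_value
  summary <- data.frame(
    mean_lifespan_ref = ml_ref, mean_lifespan_pred = ml_pred,
    halt_day = if (is.na(hr$halt_day)) NA_integer_ else hr$halt_day,
    mae_percent = mae_nn, p_value = p_ref_pred,
    baseline_mae_percent = mae_base,
    baseline_a = if (is.null(base)) NA_real_ else base$a,
    baseline_b = if (is.null(base)) NA_real_ else base$b)
  structure(list(summary = summary, halt_report = hr, reference = ref,
                 predicted_curve = pred_curve,
                 baseline_curve = if (is.null(base)) NULL else base$fitted,
                 eval_days = eval_days),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  s <- x$summary
  cat("<evaluation_report>\n")
  cat(sprintf("  mean lifespan: ref %.2f / predicted %.2f days\n",
              s$mean_lifespan_ref, s$mean_lifespan_pred))
  cat(sprintf("  halt day: %s\n",
              ifelse(is.na(s$halt_day), "none", s$halt_day)))
  cat(sprintf("  MAE %.2f%% (Weibull-fit baseline %.2f%%), log-rank p = %.3f\n",
              s$mae_percent, s$baseline_mae_percent, s$p_value))
  invisible(x)
}
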
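# Flat-file interfaces: everything on disk is plain CSV, PNG or YAML, with
# 0-based day indices throughout.

#' Write lifespan curves to CSV
#'
#' Columns `plate_id, day, live_count, initial_count`, one row per capture
#' day, days 0-based.
#'
#' @param curves A [lifespan_curve()] or list of them.
#' @param path Output CSV path.
#' @return Invisibly, the written data frame.
#' @export
write_curves <- function(curves, path) {
  if (inherits(curves, "lifespan_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read lifespan curves from CSV
#'
#' @param path CSV written by [write_curves()].
#' @return Named list of [lifespan_curve()], one per `plate_id`.
#' @export
read_curves <- function(path) {
  df <- utils::read.csv(path)
  out <- lapply(split(df, df$plate_id), function(d) {
    d <- d[order(d$day), ]
    lifespan_curve(d$live_count, plate_id = as.character(d$plate_id[1L]))
  })
  out[unique(as.character(df$plate_id))]
}

#' Write worm trajectories to CSV
#'
#' Columns `plate_id, worm_id, day, x, y, alive` (pixel units, 0-based
#' days).
#'
#' @param trajectories A `worm_trajectories` or list of them.
#' @param path Output CSV path.
#' @return Invisibly, the written data frame.
#' @export
write_trajectories <- function(trajectories, path) {
  if (inherits(trajectories, "worm_trajectories"))
    trajectories <- list(trajectories)
  df <- do.call(rbind, lapply(trajectories, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write a condition band to CSV
#'
#' Columns `day, mean, std, ci_lower, ci_upper`.
#'
#' @param band A `condition_band`.
#' @param path Output CSV path.
#' @return Invisibly, the written data frame.
#' @export
write_band <- function(band, path) {
  df <- as.data.frame(band)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write a halting report to CSV
#'
#' Per-day trace `day, p_value, statistic, halt` plus a summary comment
#' line.
#'
#' @param report A `halt_report`.
#' @param path Output CSV path.
#' @return Invisibly, the trace data frame.
#' @export
write_halt_report <- function(report, path) {
  utils::write.csv(report$trace, path, row.names = FALSE)
  invisible(report$trace)
}

#' Save / load a trained predictor
#'
#' The checkpoint bundles the configuration, the parameters and the loss
#' history.
#'
#' @param predictor A `worm_predictor`.
#' @param path Checkpoint path (RDS).
#' @return `save_predictor` returns the path invisibly; `load_predictor`
#'   the predictor.
#' @export
save_predictor <- function(predictor, path) {
  stopifnot(inherits(predictor, "worm_predictor"))
  saveRDS(predictor, path)
  invisible(path)
}

#' @rdname save_predictor
#' @export
load_predictor <- function(path) {
  p <- readRDS(path)
  stopifnot(inherits(p, "worm_predictor"))
  p
}

#' Load / save a flat run configuration (YAML)
#'
#' @param path YAML file path.
#' @return `config_load` returns a named list; `config_save` the path,
#'   invisibly.
#' @export
config_load <- function(path) yaml::read_yaml(path)

#' @rdname config_load
#' @param config Named list to serialise.
#' @export
config_save <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
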
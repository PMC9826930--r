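#' Synthetic-domain image geometry
#'
#' The model never sees micrographs: every capture day is reduced to a
#' synthetic-domain image -- filled circles at the worm centroids on a
#' constant gray background. The same representation is produced by the
#' simulator and (upstream of this package) by detection networks applied to
#' real captures, which is what lets a simulator-trained model run on real
#' assays.
#'
#' @param side Square image side length in pixels (default 64).
#' @param background_level Background gray intensity in `[0, 255]`
#'   (default 128).
#' @param blob_radius Circle radius in pixels (default 2, `>= 1`).
#' @param blob_level Circle intensity in `[0, 255]`, different from the
#'   background (default 255).
#' @return An object of class `image_spec`.
#' @export
image_spec <- function(side = 64L, background_level = 128L, blob_radius = 2L,
                       blob_level = 255L) {
  side <- as.integer(side); blob_radius <- as.integer(blob_radius)
  stopifnot(blob_radius >= 1L, side >= 4L * blob_radius,
            background_level >= 0, background_level <= 255,
            blob_level >= 0, blob_level <= 255)
  if (blob_level == background_level)
    stop("blob_level must differ from background_level", call. = FALSE)
  structure(list(side = side, background_level = as.integer(background_level),
                 blob_radius = blob_radius, blob_level = as.integer(blob_level)),
            class = "image_spec")
}

# Precompute integer pixel offsets of a filled circle of radius r.
disc_offsets <- function(r) {
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE]
}

#' Render one synthetic-domain frame
#'
#' Draws a filled circle of `spec$blob_radius` at each worm centroid on a
#' constant gray background. Circle centres are rounded to the pixel grid;
#' overlapping circles merge into a flat region at `blob_level`. Positions
#' outside the image raise an error rather than being clipped silently
#' (circle pixels spilling over the border from an in-bounds centre are
#' simply not drawn).
#'
#' @param positions Numeric matrix `[n, 2]` of (x, y) pixel coordinates
#'   (origin top-left, x rightward, y downward, 0-based), or `NULL`/empty for
#'   a background-only frame.
#' @param spec An [image_spec()].
#' @return Integer matrix `[side, side]` of intensities in `[0, 255]`; rows
#'   index y, columns index x.
#' @export
render_frame <- function(positions, spec = image_spec()) {
  stopifnot(inherits(spec, "image_spec"))
  img <- matrix(spec$background_level, spec$side, spec$side)
  if (is.null(positions) || NROW(positions) == 0L) return(img)
  positions <- matrix(as.numeric(positions), ncol = 2L)
  if (any(!is.finite(positions)) ||
      any(positions < 0) || any(positions > spec$side - 1))
    stop("worm position outside image bounds", call. = FALSE)
  off <- disc_offsets(spec$blob_radius)
  cx <- round(positions[, 1L]); cy <- round(positions[, 2L])
  px <- rep(cx, each = nrow(off)) + off$dx
  py <- rep(cy, each = nrow(off)) + off$dy
  keep <- px >= 0L & px < spec$side & py >= 0L & py < spec$side
  img[cbind(py[keep] + 1L, px[keep] + 1L)] <- spec$blob_level
  img
}

#' Render the full per-day frame sequence of a plate
#'
#' Frame `d` shows every worm (alive and dead) at its day-`d` position; dead
#' worms appear at their frozen position in all subsequent frames, so the
#' pixel difference between consecutive frames is zero exactly where nothing
#' moved.
#'
#' @param trajectories A `worm_trajectories` object from
#'   [sample_trajectories()].
#' @param spec An [image_spec()].
#' @return An object of class `frame_sequence`: list with `frames` (list of
#'   integer matrices), `day_index` (0-based), and the `image_spec` used.
#' @export
render_sequence <- function(trajectories, spec = image_spec()) {
  stopifnot(inherits(trajectories, "worm_trajectories"))
  n_days <- dim(trajectories$positions)[3]
  frames <- lapply(seq_len(n_days), function(d)
    render_frame(matrix(trajectories$positions[, , d], ncol = 2L), spec))
  structure(list(frames = frames, day_index = 0:(n_days - 1L), spec = spec,
                 plate_id = trajectories$plate_id),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat("<frame_sequence> ", length(x$frames), " frames, ",
      x$spec$side, "x", x$spec$side, " px\n", sep = "")
  invisible(x)
}

#' Write a frame sequence to PNG files
#'
#' One 8-bit grayscale PNG per day, named `plate{ID}_day{D}.png`, plus a
#' manifest data frame linking plate, day and file path.
#'
#' @param fs A `frame_sequence`.
#' @param dir Output directory (created if missing).
#' @param plate_id Identifier used in file names; defaults to the sequence's.
#' @return Invisibly, the manifest `data.frame(plate_id, day, path)`.
#' @export
write_frames <- function(fs, dir, plate_id = fs$plate_id) {
  stopifnot(inherits(fs, "frame_sequence"))
  if (is.na(plate_id)) plate_id <- "0"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("plate%s_day%d.png", plate_id, fs$day_index))
  for (i in seq_along(fs$frames))
    png::writePNG(fs$frames[[i]] / 255, paths[i])
  invisible(data.frame(plate_id = plate_id, day = fs$day_index, path = paths))
}

#' Read a frame sequence back from a PNG manifest
#'
#' @param manifest Data frame with columns `day` and `path` (as written by
#'   [write_frames()]).
#' @param spec The [image_spec()] the frames were rendered with.
#' @return A `frame_sequence`.
#' @export
read_frames <- function(manifest, spec) {
  manifest <- manifest[order(manifest$day), , drop = FALSE]
  frames <- lapply(manifest$path, function(p) {
    m <- png::readPNG(p)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  })
  structure(list(frames = frames, day_index = as.integer(manifest$day),
                 spec = spec, plate_id = manifest$plate_id[1L]),
            class = "frame_sequence")
}
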
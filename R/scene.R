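#' Configure the synthetic camera scene
#'
#' Builds the static part of a synthetic visual scene: a mixed-color background
#' (sampled pixelwise from `background_palette`) in which a fraction
#' `distractor_red_fraction` of pixels is recolored to the target hue, standing
#' in for non-target red objects in the field of view. The moving target itself
#' is rendered per frame by [render_frame()] as a solid axis-aligned rectangle
#' of pure `target_hue`, vertically centered.
#'
#' The background and the distractor field are drawn once from `seed` and
#' cached, so the scene is static across frames and frames are bit-identical
#' for identical configurations. The distractor fraction should stay well below
#' the level at which background pixels alone could flip the sign of the
#' left/right strip difference downstream (with the defaults, roughly 1500
#' distractor pixels spread uniformly contribute a strip imbalance far below
#' one 500-pixel stimulation quantum).
#'
#' @param frame_width,frame_height Frame size in pixels.
#' @param target_hue Target hue in degrees, in `[0, 360)`. Default 0 (red).
#' @param target_width,target_height Target rectangle size in pixels.
#' @param background_palette Character vector of R colors used for non-target
#'   background pixels; they must not fall inside the red hue gate.
#' @param distractor_red_fraction Fraction in `[0, 1)` of background pixels
#'   recolored to the target hue.
#' @param seed Integer seed for the background/distractor field.
#' @return An object of class `nl_scene`.
#' @seealso [render_frame()], [sample_trajectory()]
#' @export
#' @examples
#' sc <- scene_config(frame_width = 200, frame_height = 100,
#'                    distractor_red_fraction = 0)
#' fr <- render_frame(sc, target_px_offset = 0)
scene_config <- function(frame_width = 640, frame_height = 480,
                         target_hue = 0, target_width = 200, target_height = 100,
                         background_palette = c("gray70", "forestgreen",
                                                "steelblue", "goldenrod"),
                         distractor_red_fraction = 0.005, seed = 1L) {
  if (frame_width <= 0 || frame_height <= 0)
    stop_cfg("frame dimensions must be positive")
  if (target_width <= 0 || target_height <= 0)
    stop_cfg("target dimensions must be positive")
  if (target_width > frame_width || target_height > frame_height)
    stop_cfg("target must fit inside the frame")
  if (target_hue < 0 || target_hue >= 360)
    stop_cfg("target_hue must be in [0, 360)")
  if (distractor_red_fraction < 0 || distractor_red_fraction >= 1)
    stop_cfg("distractor_red_fraction must be in [0, 1)")

  target_rgb <- as.integer(
    grDevices::col2rgb(grDevices::hsv(target_hue / 360, 1, 1))[, 1])
  pal_rgb <- grDevices::col2rgb(background_palette)

  cache <- eval_with_seed(seed, function() {
    n <- frame_width * frame_height
    list(
      pal_index  = matrix(sample.int(ncol(pal_rgb), n, replace = TRUE),
                          frame_height, frame_width),
      distractor = matrix(stats::runif(n) < distractor_red_fraction,
                          frame_height, frame_width)
    )
  })

  bg <- array(0L, c(frame_height, frame_width, 3L))
  for (k in 1:3) {
    plane <- matrix(pal_rgb[k, cache$pal_index], frame_height, frame_width)
    plane[cache$distractor] <- target_rgb[k]
    bg[, , k] <- plane
  }

  row0 <- (frame_height - target_height) %/% 2L + 1L
  rows <- row0:(row0 + target_height - 1L)

  structure(list(
    frame_width = as.integer(frame_width),
    frame_height = as.integer(frame_height),
    target_hue = target_hue,
    target_width = as.integer(target_width),
    target_height = as.integer(target_height),
    background_palette = background_palette,
    distractor_red_fraction = distractor_red_fraction,
    seed = seed,
    target_rgb = target_rgb,
    target_rows = rows,
    background = bg,
    distractor = cache$distractor,
    distractor_cols_all = colSums(cache$distractor),
    distractor_cols_band = colSums(cache$distractor[rows, , drop = FALSE])
  ), class = "nl_scene")
}

# Columns occupied by the target for a given pixel offset of the target center
# from the frame center; integer(0) when the target is absent.
target_columns <- function(scene, target_px_offset) {
  if (is.null(target_px_offset) || length(target_px_offset) == 0 ||
      is.na(target_px_offset)) return(integer(0))
  left <- as.integer(round((scene$frame_width - scene$target_width) / 2 +
                             target_px_offset)) + 1L
  cols <- seq.int(left, left + scene$target_width - 1L)
  cols <- cols[cols >= 1L & cols <= scene$frame_width]
  if (length(cols) == 0)
    stop_cfg("target_px_offset places no target column inside the frame; ",
             "use NA for an absent target")
  cols
}

#' Render one synthetic camera frame
#'
#' Overlays the target rectangle (if present) on the cached scene background.
#' `target_px_offset` is the horizontal offset, in pixels, of the target center
#' from the frame center; `NA` (or `NULL`) renders a target-absent frame.
#' Identical scene and offset give bit-identical frames.
#'
#' @param scene An `nl_scene` from [scene_config()].
#' @param target_px_offset Pixel offset of the target center from the frame
#'   center, or `NA` for an absent target.
#' @return An `nl_frame`: list with `width`, `height` and `pixels`, an
#'   `height x width x 3` integer array of RGB values in `[0, 255]`.
#' @export
render_frame <- function(scene, target_px_offset = NA) {
  stopifnot(inherits(scene, "nl_scene"))
  px <- scene$background
  cols <- target_columns(scene, target_px_offset)
  if (length(cols)) {
    for (k in 1:3) px[scene$target_rows, cols, k] <- scene$target_rgb[k]
  }
  structure(list(width = scene$frame_width, height = scene$frame_height,
                 pixels = px), class = "nl_frame")
}

# Exact white-pixel count per frame column after red-hue thresholding, without
# rasterizing: distractor pixels count everywhere except where the target
# rectangle overwrites them; target columns contribute the full target height.
# Verified against the full render -> threshold pipeline in the test suite.
scene_column_white <- function(scene, target_px_offset = NA) {
  w <- scene$distractor_cols_all
  cols <- target_columns(scene, target_px_offset)
  if (length(cols)) {
    w[cols] <- w[cols] - scene$distractor_cols_band[cols] + scene$target_height
  }
  w
}

#' Specify a target trajectory
#'
#' A trajectory gives the target's horizontal position (inches, arm frame,
#' 0 = midpoint) as a function of time, with optional intervals during which
#' the target is out of the camera's field of view entirely (e.g. removed by
#' the experimenter). Constructors: [trajectory_static()], [trajectory_sweep()],
#' [trajectory_piecewise()], [trajectory_fullrange()].
#'
#' @param kind One of `"static"`, `"sweep"`, `"piecewise"`.
#' @param duration Total duration in seconds (> 0).
#' @param times,positions Knot times (seconds) and positions (inches) for
#'   piecewise-linear interpolation; for `"static"` a single position.
#' @param absent_windows List of 2-vectors `c(a, b)`; the target is absent for
#'   `a <= t < b`.
#' @return An object of class `nl_trajectory`.
#' @export
trajectory_spec <- function(kind, duration, times, positions,
                            absent_windows = list()) {
  kind <- match.arg(kind, c("static", "sweep", "piecewise"))
  if (!is.numeric(duration) || duration <= 0)
    stop_cfg("duration must be positive")
  if (length(times) != length(positions) || length(times) < 1)
    stop_cfg("times and positions must have equal positive length")
  if (is.unsorted(times)) stop_cfg("times must be nondecreasing")
  for (w in absent_windows) {
    if (length(w) != 2 || w[1] >= w[2])
      stop_cfg("each absent window must be c(a, b) with a < b")
  }
  structure(list(kind = kind, duration = duration, times = times,
                 positions = positions, absent_windows = absent_windows),
            class = "nl_trajectory")
}

#' @rdname trajectory_spec
#' @param position Constant position in inches.
#' @export
trajectory_static <- function(position, duration, absent_windows = list()) {
  trajectory_spec("static", duration, c(0, duration), c(position, position),
                  absent_windows)
}

#' @rdname trajectory_spec
#' @param from,to Sweep endpoints in inches (linear, one-way).
#' @export
trajectory_sweep <- function(from = -5, to = 5, duration = 10,
                             absent_windows = list()) {
  trajectory_spec("sweep", duration, c(0, duration), c(from, to),
                  absent_windows)
}

#' @rdname trajectory_spec
#' @export
trajectory_piecewise <- function(times, positions, duration = max(times),
                                 absent_windows = list()) {
  trajectory_spec("piecewise", duration, times, positions, absent_windows)
}

#' @rdname trajectory_spec
#' @param extent Half-range in inches; the full-range trajectory runs midpoint
#'   -> `+extent` -> `-extent` -> midpoint over `duration` ("full left to full
#'   right and back again").
#' @export
trajectory_fullrange <- function(extent = 5, duration = 120,
                                 absent_windows = list()) {
  trajectory_piecewise(
    times = c(0, duration / 4, 3 * duration / 4, duration),
    positions = c(0, extent, -extent, 0),
    duration = duration, absent_windows = absent_windows)
}

#' Sample a trajectory at given times
#'
#' @param spec An `nl_trajectory`.
#' @param t Time(s) in seconds, each within `[0, duration]`.
#' @return Numeric vector of positions in inches, with `NA` wherever the
#'   target is absent.
#' @export
sample_trajectory <- function(spec, t) {
  stopifnot(inherits(spec, "nl_trajectory"))
  if (any(t < 0 | t > spec$duration))
    stop_cfg("t must lie within [0, duration]")
  x <- stats::approx(spec$times, spec$positions, xout = t, rule = 2)$y
  for (w in spec$absent_windows) x[t >= w[1] & t < w[2]] <- NA_real_
  x
}

#' Read and write frames as PNG
#'
#' @param frame An `nl_frame`.
#' @param path File path.
#' @return `read_frame_png()` returns an `nl_frame`; `write_frame_png()`
#'   returns `path` invisibly.
#' @export
write_frame_png <- function(frame, path) {
  stopifnot(inherits(frame, "nl_frame"))
  png::writePNG(frame$pixels / 255, target = path)
  invisible(path)
}

#' @rdname write_frame_png
#' @export
read_frame_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  px <- array(as.integer(round(a[, , 1:3] * 255)), c(dim(a)[1:2], 3L))
  structure(list(width = dim(a)[2], height = dim(a)[1], pixels = px),
            class = "nl_frame")
}

#' Write a sampled trajectory as CSV
#'
#' Columns: `t`, `x_inches`, `visible`.
#'
#' @param spec An `nl_trajectory`.
#' @param path File path.
#' @param dt Sampling interval in seconds.
#' @export
write_trajectory_csv <- function(spec, path, dt = 0.1) {
  t <- seq(0, spec$duration, by = dt)
  x <- sample_trajectory(spec, t)
  utils::write.csv(
    data.frame(t = t, x_inches = x, visible = !is.na(x)),
    path, row.names = FALSE)
  invisible(path)
}
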
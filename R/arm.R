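#' One-dimensional robot arm state
#'
#' The arm moves left/right at constant speed along a rail of half-length
#' `range` inches, midpoint at 0. The camera is rigidly mounted on the arm,
#' so the camera view center always equals the arm position.
#'
#' @param position Initial position in inches, within `[-range, range]`.
#' @param speed Travel speed in inches/s (> 0). Default 0.25 (one 0.25-inch
#'   tracking-tolerance unit per second; see the methods vignette).
#' @param range Half-range in inches (> 0). Default 10.
#' @return An `nl_arm`: list with `position`, `speed`, `range`.
#' @export
arm_state <- function(position = 0, speed = 0.25, range = 10) {
  if (speed <= 0) stop_cfg("speed must be positive")
  if (range <= 0) stop_cfg("range must be positive")
  if (abs(position) > range) stop_cfg("position must lie within [-range, range]")
  structure(list(position = position, speed = speed, range = range),
            class = "nl_arm")
}

#' Apply a motion command to the arm
#'
#' `MOVE_LEFT`/`MOVE_RIGHT` shift the position by `-speed * dt` /
#' `+speed * dt`, clamped to the rail; `STOP` leaves it unchanged.
#'
#' @param arm An `nl_arm`.
#' @param command `"MOVE_LEFT"`, `"MOVE_RIGHT"` or `"STOP"`.
#' @param dt Time step in seconds (> 0).
#' @return The updated `nl_arm`.
#' @export
apply_command <- function(arm, command, dt) {
  stopifnot(inherits(arm, "nl_arm"))
  if (dt <= 0) stop_cfg("dt must be positive")
  command <- match.arg(command, c("MOVE_LEFT", "MOVE_RIGHT", "STOP"))
  delta <- switch(command,
                  MOVE_LEFT = -arm$speed * dt,
                  MOVE_RIGHT = arm$speed * dt,
                  STOP = 0)
  arm$position <- min(arm$range, max(-arm$range, arm$position + delta))
  arm
}

#' Arm-mounted camera model
#'
#' Linear projection of target position into the camera frame: the view is
#' centered on the arm, spans `field_of_view` inches, and maps inches to
#' pixels at `frame_width / field_of_view` pixels per inch.
#'
#' @param field_of_view Horizontal field of view in inches (> 0). Default 10.
#' @param frame_width Frame width in pixels.
#' @return An `nl_camera`: list with `field_of_view`, `frame_width`,
#'   `pixels_per_inch`.
#' @export
camera_model <- function(field_of_view = 10, frame_width = 640) {
  if (field_of_view <= 0 || frame_width <= 0)
    stop_cfg("field_of_view and frame_width must be positive")
  structure(list(field_of_view = field_of_view, frame_width = frame_width,
                 pixels_per_inch = frame_width / field_of_view),
            class = "nl_camera")
}

#' Pixel offset of the target in the arm-mounted camera view
#'
#' @param cam An `nl_camera`.
#' @param arm An `nl_arm`.
#' @param target_pos Target position in inches, or `NA` if absent.
#' @return Pixel offset of the target center from the frame center, or `NA`
#'   if the target is absent or its center lies outside the field of view.
#' @export
view_offset <- function(cam, arm, target_pos) {
  stopifnot(inherits(cam, "nl_camera"), inherits(arm, "nl_arm"))
  if (is.na(target_pos)) return(NA_real_)
  d <- target_pos - arm$position
  if (abs(d) > cam$field_of_view / 2) return(NA_real_)
  d * cam$pixels_per_inch
}

#' Return-to-midpoint homing step
#'
#' When the target has been absent from the camera view for at least
#' `homing_after` consecutive frames, the arm moves toward the midpoint (0)
#' at its travel speed, stopping exactly at 0; otherwise the arm is left
#' unchanged.
#'
#' @param arm An `nl_arm`.
#' @param frames_without_target Count of consecutive target-absent frames.
#' @param homing_after Threshold count H (>= 1). Default 10.
#' @param dt Time step in seconds.
#' @return The updated `nl_arm`.
#' @export
homing_step <- function(arm, frames_without_target, homing_after = 10, dt = 0.2) {
  stopifnot(inherits(arm, "nl_arm"))
  if (homing_after < 1) stop_cfg("homing_after must be >= 1")
  if (frames_without_target < homing_after) return(arm)
  step <- arm$speed * dt
  arm$position <- sign(arm$position) * max(0, abs(arm$position) - step)
  arm
}
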
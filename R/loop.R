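empty_stim <- function() {
  data.frame(time = numeric(0), side = character(0), count = integer(0))
}

# Simulate one arbitrary-length trace segment under the currently active
# stimulation schedule (stim times may predate t0; their evoked windows are
# clipped to the segment). Uses the current RNG stream.
sim_segment <- function(cfg, layout, stim, t0, t1) {
  n <- round((t1 - t0) * cfg$sample_rate)
  samples <- matrix(stats::rnorm(60L * n, sd = cfg$noise_sd), nrow = 60L)
  out <- inject_spikes(cfg, layout, stim, t0, t1, samples)
  structure(list(t0 = t0, duration = t1 - t0, sample_rate = cfg$sample_rate,
                 samples = out$samples, truth = out$truth),
            class = "nl_window")
}

#' Configure a closed-loop run
#'
#' Bundles every stage's configuration plus the loop's own scheduling
#' parameters. Frames are captured at `frame_rate`; each frame's stimulus is
#' delivered to the network at the frame time; recording windows tile the run
#' in 3-s blocks, with channel statistics refreshed as each window completes
#' (the first window uses statistics from a 3-s spontaneous calibration
#' period simulated before the run); decisions fall on the `decision_period`
#' grid and move the arm immediately.
#'
#' @param scene An `nl_scene`.
#' @param trajectory An `nl_trajectory`.
#' @param network An `nl_network_config`.
#' @param refs An `nl_refs` (decoder templates).
#' @param arm An `nl_arm`.
#' @param camera An `nl_camera`; its frame width must match the scene.
#' @param beta Activation decay constant, 1/s.
#' @param decision_period Seconds between motion decisions. Default 0.2.
#' @param quantum Pixel quantum per synaptic signal. Default 500.
#' @param hue_tol,sat_min,val_min Vision thresholds (see [threshold_hue()]);
#'   the hue center is the scene's target hue.
#' @param frame_rate Camera frames per second. Default 10.
#' @param duration Run length in seconds; must be a positive multiple of the
#'   3-s recording window.
#' @param homing_after Consecutive target-absent frames after which the arm
#'   homes to the midpoint; `Inf` disables homing.
#' @param absent_white_min Minimum white-pixel count for the target to count
#'   as seen.
#' @param tolerance Tracking tolerance in inches for the report. Default 0.25.
#' @param seed Integer seed; the whole run is deterministic given the config.
#' @param fast_vision Use the exact closed-form white-pixel counts instead of
#'   rasterizing every frame (the two paths are verified identical in the
#'   test suite).
#' @return An object of class `nl_loop_config`.
#' @export
loop_config <- function(scene = scene_config(),
                        trajectory = trajectory_fullrange(),
                        network = network_config(),
                        refs = reference_vectors(),
                        arm = arm_state(),
                        camera = camera_model(frame_width = scene$frame_width),
                        beta = 5, decision_period = 0.2, quantum = 500,
                        hue_tol = 10, sat_min = 0.5, val_min = 0.3,
                        frame_rate = 10, duration = 120,
                        homing_after = 10, absent_white_min = 5000,
                        tolerance = 0.25, seed = 1, fast_vision = TRUE) {
  stopifnot(inherits(scene, "nl_scene"), inherits(trajectory, "nl_trajectory"),
            inherits(network, "nl_network_config"), inherits(refs, "nl_refs"),
            inherits(arm, "nl_arm"), inherits(camera, "nl_camera"))
  if (camera$frame_width != scene$frame_width)
    stop_cfg("camera frame_width must match the scene frame width")
  if (duration < 3 || abs(duration / 3 - round(duration / 3)) > 1e-9)
    stop_cfg("duration must be a positive multiple of the 3-s window")
  frame_dt <- 1 / frame_rate
  spd <- decision_period / frame_dt
  if (abs(spd - round(spd)) > 1e-9)
    stop_cfg("decision_period must be a multiple of the frame period")
  if (abs(3 / decision_period - round(3 / decision_period)) > 1e-9)
    stop_cfg("the 3-s window must hold an integer number of decisions")
  if (trajectory$duration < duration)
    stop_cfg("trajectory must cover the run duration")
  structure(list(scene = scene, trajectory = trajectory, network = network,
                 refs = refs, arm = arm, camera = camera, beta = beta,
                 decision_period = decision_period, quantum = quantum,
                 hue_tol = hue_tol, sat_min = sat_min, val_min = val_min,
                 frame_rate = frame_rate, duration = duration,
                 homing_after = homing_after,
                 absent_white_min = absent_white_min,
                 tolerance = tolerance, seed = seed,
                 fast_vision = fast_vision),
            class = "nl_loop_config")
}

#' Run the closed loop
#'
#' Executes the full pipeline on a shared simulated clock: at each frame tick
#' the scene is rendered from the arm-mounted camera's viewpoint,
#' hue-thresholded, strip-summed and quantized into a stimulation batch; the
#' batch drives the network simulator for the next frame interval; spikes are
#' detected against the statistics of the last completed 3-s window; at each
#' decision tick the activation vector is updated, classified, and the
#' resulting command (or the homing override after sustained target absence)
#' moves the arm. Deterministic for a fixed config.
#'
#' @param cfg An `nl_loop_config`.
#' @return An `nl_tracking_run`: list with `config`, `decisions`, `stimuli`,
#'   `windows` data frames and `report` (see [tracking_report()]).
#' @export
run_loop <- function(cfg) {
  stopifnot(inherits(cfg, "nl_loop_config"))
  set.seed(cfg$seed)
  layout <- mea_layout()
  net <- cfg$network
  arm <- cfg$arm
  frame_dt <- 1 / cfg$frame_rate
  steps_per_dec <- round(cfg$decision_period / frame_dt)
  n_steps <- round(cfg$duration * cfg$frame_rate)
  win_len <- round(3 * net$sample_rate)

  # Spontaneous calibration period: channel statistics for the first window.
  stats <- channel_stats(sim_segment(net, layout, empty_stim(), -3, 0))

  state <- activation_state(nrow(layout), beta = cfg$beta, t0 = 0)
  active <- empty_stim()
  absent_frames <- 0L
  buffer <- vector("list", 0)
  buf_cols <- 0L
  win_t0 <- 0
  seg_events <- vector("list", 0)

  stim_rows <- vector("list", n_steps)
  dec_rows <- vector("list", n_steps %/% steps_per_dec)
  win_rows <- vector("list", round(cfg$duration / 3))
  win_i <- 0L; dec_i <- 0L

  for (step in seq_len(n_steps)) {
    t_f <- (step - 1L) * frame_dt
    target <- sample_trajectory(cfg$trajectory, t_f)
    off <- view_offset(cfg$camera, arm, target)

    if (cfg$fast_vision) {
      colw <- scene_column_white(cfg$scene, off)
      sums <- strip_sums_from_columns(colw)
      white <- sum(colw)
    } else {
      fr <- render_frame(cfg$scene, off)
      vs <- frame_to_stimulus(fr, hue_center = cfg$scene$target_hue,
                              hue_tol = cfg$hue_tol, sat_min = cfg$sat_min,
                              val_min = cfg$val_min, quantum = cfg$quantum)
      sums <- vs$sums
      white <- vs$white_count
    }
    st <- stimulus_from_sums(sums, cfg$quantum)
    seen <- white >= cfg$absent_white_min
    absent_frames <- if (seen) 0L else absent_frames + 1L

    if (st$side != "NONE")
      active <- rbind(active, data.frame(time = t_f, side = st$side,
                                         count = st$count))
    active <- active[active$time + net$evoked_duration > t_f, , drop = FALSE]

    seg <- sim_segment(net, layout, active, t_f, t_f + frame_dt)
    buffer[[length(buffer) + 1L]] <- seg$samples
    buf_cols <- buf_cols + ncol(seg$samples)
    seg_events[[length(seg_events) + 1L]] <- detect_spikes(seg, stats = stats)

    stim_rows[[step]] <- data.frame(
      frame = step, t = t_f,
      s1 = sums$sums[1], s2 = sums$sums[2], s3 = sums$sums[3],
      s4 = sums$sums[4], s5 = sums$sums[5],
      left3 = sums$left3, right3 = sums$right3, white = white,
      side = st$side, count = st$count,
      target_pos = target, offset_px = off, seen = seen)

    if (buf_cols >= win_len) {
      win <- structure(list(t0 = win_t0, duration = 3,
                            sample_rate = net$sample_rate,
                            samples = do.call(cbind, buffer), truth = NULL),
                       class = "nl_window")
      stats <- channel_stats(win)
      win_i <- win_i + 1L
      win_rows[[win_i]] <- data.frame(window = win_i, t0 = win_t0,
                                      mean_sd = mean(stats$sd))
      buffer <- vector("list", 0)
      buf_cols <- 0L
      win_t0 <- win_t0 + 3
    }

    if (step %% steps_per_dec == 0L) {
      t_d <- step * frame_dt
      ev <- do.call(rbind, seg_events)
      seg_events <- vector("list", 0)
      state <- update_activation(state, ev, t_d)
      cls <- classify_activation(state, cfg$refs)
      homing <- is.finite(cfg$homing_after) &&
        absent_frames >= cfg$homing_after
      if (homing) {
        arm <- homing_step(arm, absent_frames, cfg$homing_after,
                           cfg$decision_period)
      } else {
        arm <- apply_command(arm, cls$command, cfg$decision_period)
      }
      tgt_d <- sample_trajectory(cfg$trajectory, t_d)
      dec_i <- dec_i + 1L
      dec_rows[[dec_i]] <- data.frame(
        t = t_d, d_L = cls$d_L, d_R = cls$d_R, command = cls$command,
        homing = homing, arm_pos = arm$position, target_pos = tgt_d,
        error = abs(arm$position - tgt_d), n_events = nrow(ev))
    }
  }

  decisions <- do.call(rbind, dec_rows)
  run <- structure(list(
    config = cfg,
    decisions = decisions,
    stimuli = do.call(rbind, stim_rows),
    windows = do.call(rbind, win_rows[seq_len(win_i)])),
    class = "nl_tracking_run")
  run$report <- tracking_report(run, tolerance = cfg$tolerance)
  run
}

#' Time-weighted within-tolerance tracking fraction
#'
#' Fraction of the target-present ticks at which the arm-target distance is
#' below `tolerance`. Ticks must share a common time base.
#'
#' @param time Tick times (seconds).
#' @param arm_pos,target_pos Arm and target positions in inches at each tick;
#'   `NA` target positions mark target-absent ticks, which are excluded.
#' @param tolerance Tolerance in inches. Default 0.25.
#' @return Fraction in `[0, 1]` (`NaN` when the target is never present).
#' @export
tracking_fraction <- function(time, arm_pos, target_pos, tolerance = 0.25) {
  if (length(time) != length(arm_pos) || length(time) != length(target_pos))
    stop_cfg("time, arm_pos and target_pos must share one time base")
  present <- !is.na(target_pos)
  mean(abs(arm_pos[present] - target_pos[present]) < tolerance)
}

#' Summarize a closed-loop run
#'
#' Reports the within-tolerance fraction over the target-present observation
#' period, mean/max absolute error, and the arm trajectory quantized to
#' 0.25-inch increments (net movement is recorded in these pre-defined
#' increments rather than raw pixels).
#'
#' @param run An `nl_tracking_run`.
#' @param tolerance Tolerance in inches. Default 0.25.
#' @return List with `within_tolerance_fraction`, `tolerance`,
#'   `n_ticks_present`, `n_ticks`, `mean_abs_error`, `max_abs_error` and
#'   `quantized` (data frame `t`, `arm_pos_q`).
#' @export
tracking_report <- function(run, tolerance = 0.25) {
  stopifnot(inherits(run, "nl_tracking_run"))
  d <- run$decisions
  present <- !is.na(d$target_pos)
  list(
    within_tolerance_fraction =
      tracking_fraction(d$t, d$arm_pos, d$target_pos, tolerance),
    tolerance = tolerance,
    n_ticks_present = sum(present),
    n_ticks = nrow(d),
    mean_abs_error = mean(d$error[present]),
    max_abs_error = if (any(present)) max(d$error[present]) else NA_real_,
    quantized = data.frame(t = d$t,
                           arm_pos_q = round(d$arm_pos / 0.25) * 0.25))
}

#' @export
print.nl_tracking_run <- function(x, ...) {
  r <- x$report
  cat("Closed-loop tracking run\n")
  cat(sprintf("  duration: %g s, seed: %s\n",
              x$config$duration, format(x$config$seed)))
  cat(sprintf("  decisions: %d (%d with target present)\n",
              r$n_ticks, r$n_ticks_present))
  cat(sprintf("  within %.2f\" of target: %.1f%% of observation period\n",
              r$tolerance, 100 * r$within_tolerance_fraction))
  cat(sprintf("  mean |error|: %.3f\", max |error|: %.3f\"\n",
              r$mean_abs_error, r$max_abs_error))
  invisible(x)
}

#' Multi-seed tracking experiment
#'
#' Runs the closed loop once per seed and aggregates the within-tolerance
#' fractions as mean and SD across seeds (each seed standing in for one
#' network preparation).
#'
#' @param cfg An `nl_loop_config` (its `seed` is overridden per run).
#' @param seeds Integer vector of seeds; default `cfg$seed - 1 + 1:n_seeds`.
#' @param n_seeds Number of seeds when `seeds` is `NULL`. Default 5.
#' @param keep_runs Keep the full run objects (memory-heavy). Default `FALSE`.
#' @return List with `per_seed` (data frame `seed`, `fraction`), `mean`,
#'   `sd`, and `runs` when kept.
#' @export
run_tracking_experiment <- function(cfg, seeds = NULL, n_seeds = 5,
                                    keep_runs = FALSE) {
  if (is.null(seeds)) seeds <- cfg$seed - 1 + seq_len(n_seeds)
  fractions <- numeric(length(seeds))
  runs <- if (keep_runs) vector("list", length(seeds)) else NULL
  for (i in seq_along(seeds)) {
    cfg$seed <- seeds[i]
    run <- run_loop(cfg)
    fractions[i] <- run$report$within_tolerance_fraction
    if (keep_runs) runs[[i]] <- run
  }
  out <- list(per_seed = data.frame(seed = seeds, fraction = fractions),
              mean = mean(fractions), sd = stats::sd(fractions))
  if (keep_runs) out$runs <- runs
  out
}

#' Net arm displacement under spontaneous activity alone
#'
#' Removes the target for the whole run and disables homing, so the arm is
#' driven purely by the network's spontaneous activity. With asymmetric
#' baseline rates, net movement favors the direction commanded by the more
#' active hemisphere.
#'
#' @param cfg An `nl_loop_config`; its trajectory is replaced by an
#'   all-absent one and homing is disabled.
#' @return List with `displacement` (inches, signed) and the full `run`.
#' @export
spontaneous_bias_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "nl_loop_config"))
  cfg$trajectory <- trajectory_static(
    0, cfg$duration, absent_windows = list(c(0, cfg$duration + 1)))
  cfg$homing_after <- Inf
  start <- cfg$arm$position
  run <- run_loop(cfg)
  list(displacement = utils::tail(run$decisions$arm_pos, 1) - start,
       run = run)
}

#' Write the logs of a run to a directory
#'
#' Writes `decisions.csv`, `stimuli.csv`, `windows.csv` and `report.json`.
#'
#' @param run An `nl_tracking_run`.
#' @param dir Output directory (created if needed).
#' @export
write_run_logs <- function(run, dir) {
  stopifnot(inherits(run, "nl_tracking_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$decisions, file.path(dir, "decisions.csv"),
                   row.names = FALSE)
  utils::write.csv(run$stimuli, file.path(dir, "stimuli.csv"),
                   row.names = FALSE)
  utils::write.csv(run$windows, file.path(dir, "windows.csv"),
                   row.names = FALSE)
  rep <- run$report
  rep$quantized <- NULL
  jsonlite::write_json(rep, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Plot target and arm trajectories of a run
#'
#' @param run An `nl_tracking_run`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_tracking <- function(run, ...) {
  stopifnot(inherits(run, "nl_tracking_run"))
  d <- run$decisions
  graphics::plot(d$t, d$target_pos, type = "l", col = "red3",
                 xlab = "time (s)", ylab = "position (inches)",
                 ylim = range(c(d$target_pos, d$arm_pos), na.rm = TRUE), ...)
  graphics::lines(d$t, d$arm_pos, col = "blue3")
  graphics::legend("topright", legend = c("target", "arm"),
                   col = c("red3", "blue3"), lty = 1, bty = "n")
  invisible(run)
}
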
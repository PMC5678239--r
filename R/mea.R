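#' The 60-electrode MEA layout
#'
#' Standard corner-less 8x8 grid: 64 lattice positions minus the four corners
#' gives 60 electrodes. The scalpel cut that segments the culture into two
#' hemispheres runs between grid columns 4 and 5, so columns 1-4 are the LEFT
#' hemisphere (30 channels) and columns 5-8 the RIGHT (30 channels).
#'
#' @return An `nl_mea_layout` data frame with columns `channel` (1..60),
#'   `row`, `col` (1..8) and `hemisphere` (`"LEFT"`/`"RIGHT"`). Channels are
#'   numbered column-major, so channels 1-30 are LEFT and 31-60 RIGHT.
#' @export
mea_layout <- function() {
  grid <- expand.grid(row = 1:8, col = 1:8)
  corner <- (grid$row %in% c(1, 8)) & (grid$col %in% c(1, 8))
  grid <- grid[!corner, ]
  grid <- grid[order(grid$col, grid$row), ]
  layout <- data.frame(
    channel = seq_len(nrow(grid)),
    row = grid$row,
    col = grid$col,
    hemisphere = ifelse(grid$col <= 4, "LEFT", "RIGHT"),
    stringsAsFactors = FALSE)
  class(layout) <- c("nl_mea_layout", "data.frame")
  layout
}

# Channel indices per hemisphere.
hemisphere_channels <- function(layout, side) {
  layout$channel[layout$hemisphere == side]
}

#' Configure the simulated network
#'
#' The cultured network is modeled at the firing-rate level: each channel
#' emits spikes from an inhomogeneous Poisson process whose rate is the
#' hemisphere's spontaneous baseline plus an evoked term proportional to the
#' number of stimulation signals currently "pending" on that hemisphere (each
#' delivered signal raises the hemisphere rate by `evoked_rate_gain` for
#' `evoked_duration` seconds, mirroring the 1-s digitized synaptic stimulus).
#' Evoked activity is confined to the stimulated hemisphere, as in the
#' segmented culture. Spikes are rendered as single-sample deflections of
#' amplitude `spike_amplitude` on top of Gaussian noise of SD `noise_sd`.
#'
#' @param baseline_rate_left,baseline_rate_right Spontaneous firing rate,
#'   spikes/s/channel, per hemisphere (>= 0). Default 2.
#' @param evoked_rate_gain Added rate, spikes/s/channel, per pending
#'   stimulation signal.
#' @param evoked_duration Seconds each signal keeps elevating the rate.
#' @param spike_amplitude Deflection amplitude in trace units; should exceed
#'   3x `noise_sd` for detectability (a warning is issued otherwise).
#' @param noise_sd Gaussian noise SD in trace units (> 0).
#' @param sample_rate Samples per second. Default 1000.
#' @param biphasic If `TRUE`, each spike is followed one sample later by a
#'   half-amplitude deflection of opposite sign.
#' @param seed Default seed for [simulate_window()]; `NULL` uses the current
#'   RNG stream.
#' @return An object of class `nl_network_config`.
#' @export
network_config <- function(baseline_rate_left = 2, baseline_rate_right = 2,
                           evoked_rate_gain = 0.5, evoked_duration = 1,
                           spike_amplitude = 6, noise_sd = 1,
                           sample_rate = 1000, biphasic = FALSE, seed = NULL) {
  if (baseline_rate_left < 0 || baseline_rate_right < 0)
    stop_cfg("baseline rates must be >= 0")
  if (evoked_rate_gain < 0) stop_cfg("evoked_rate_gain must be >= 0")
  if (evoked_duration <= 0) stop_cfg("evoked_duration must be positive")
  if (noise_sd <= 0) stop_cfg("noise_sd must be positive")
  if (sample_rate <= 0) stop_cfg("sample_rate must be positive")
  if (spike_amplitude <= 3 * noise_sd)
    warning("spike_amplitude <= 3 * noise_sd: spikes will rarely clear the ",
            "3-SD detection threshold", call. = FALSE)
  structure(list(
    baseline_rate_left = baseline_rate_left,
    baseline_rate_right = baseline_rate_right,
    evoked_rate_gain = evoked_rate_gain,
    evoked_duration = evoked_duration,
    spike_amplitude = spike_amplitude,
    noise_sd = noise_sd,
    sample_rate = sample_rate,
    biphasic = isTRUE(biphasic),
    seed = seed), class = "nl_network_config")
}

# Normalize stimulation input to a data.frame(time, side, count); rows with
# side NONE or count 0 are dropped.
as_stim_frame <- function(stim) {
  if (is.null(stim) || (is.data.frame(stim) && nrow(stim) == 0))
    return(data.frame(time = numeric(0), side = character(0),
                      count = integer(0)))
  if (!is.data.frame(stim))
    stop_cfg("stim must be a data.frame with columns time, side, count")
  if (!all(c("time", "side", "count") %in% names(stim)))
    stop_cfg("stim must have columns time, side, count")
  bad <- !stim$side %in% c("LEFT", "RIGHT", "NONE")
  if (any(bad)) stop_cfg("stim side must be LEFT, RIGHT or NONE")
  stim <- stim[stim$side != "NONE" & stim$count > 0, , drop = FALSE]
  stim[order(stim$time), , drop = FALSE]
}

# Piecewise-constant per-hemisphere firing rates over [t0, t1): returns a
# data.frame of segments (start, end, rate_left, rate_right).
rate_segments <- function(cfg, stim, t0, t1) {
  brk <- sort(unique(c(t0, t1,
                       stim$time, stim$time + cfg$evoked_duration)))
  brk <- brk[brk >= t0 & brk <= t1]
  if (brk[1] > t0) brk <- c(t0, brk)
  if (brk[length(brk)] < t1) brk <- c(brk, t1)
  starts <- brk[-length(brk)]
  ends <- brk[-1]
  pend <- function(side, s) {
    if (nrow(stim) == 0) return(0)
    on <- stim$side == side & stim$time <= s &
      s < stim$time + cfg$evoked_duration
    sum(stim$count[on])
  }
  data.frame(
    start = starts, end = ends,
    rate_left = cfg$baseline_rate_left +
      cfg$evoked_rate_gain * vapply(starts, function(s) pend("LEFT", s), 0),
    rate_right = cfg$baseline_rate_right +
      cfg$evoked_rate_gain * vapply(starts, function(s) pend("RIGHT", s), 0))
}

# Draw ground-truth spike times for all channels over [t0, t1) and add the
# deflections into `samples` (60 x n matrix, column 1 = time t0). Uses the
# current RNG stream. Returns list(samples, truth).
inject_spikes <- function(cfg, layout, stim, t0, t1, samples) {
  segs <- rate_segments(cfg, stim, t0, t1)
  n <- ncol(samples)
  ch_all <- layout$channel
  rate_for <- function(seg, side) if (side == "LEFT") seg$rate_left else seg$rate_right
  truth_ch <- integer(0); truth_t <- numeric(0)
  for (i in seq_len(nrow(segs))) {
    seg <- segs[i, ]
    len <- seg$end - seg$start
    if (len <= 0) next
    for (side in c("LEFT", "RIGHT")) {
      rate <- rate_for(seg, side)
      if (rate <= 0) next
      chans <- hemisphere_channels(layout, side)
      counts <- stats::rpois(length(chans), rate * len)
      for (j in seq_along(chans)) {
        k <- counts[j]
        if (k == 0) next
        tt <- seg$start + stats::runif(k) * len
        truth_ch <- c(truth_ch, rep.int(chans[j], k))
        truth_t <- c(truth_t, tt)
        idx <- pmin(n, floor((tt - t0) * cfg$sample_rate) + 1L)
        for (ix in idx) {
          samples[chans[j], ix] <- samples[chans[j], ix] + cfg$spike_amplitude
          if (cfg$biphasic && ix < n)
            samples[chans[j], ix + 1L] <-
              samples[chans[j], ix + 1L] - cfg$spike_amplitude / 2
        }
      }
    }
  }
  ord <- order(truth_t, truth_ch)
  list(samples = samples,
       truth = data.frame(channel = truth_ch[ord], time = truth_t[ord]))
}

#' Simulate one multichannel recording window
#'
#' Generates a 60-channel voltage window at `cfg$sample_rate` (default 3 s at
#' 1000 samples/s): Gaussian noise plus Poisson spikes whose per-hemisphere
#' rate is baseline plus the stimulation-evoked term (see [network_config()]).
#' Evoked activity is applied only to the stimulated hemisphere. The injected
#' ground-truth spike times are returned alongside the trace for detector
#' validation. Deterministic for a fixed `seed`.
#'
#' @param cfg An `nl_network_config`.
#' @param layout An `nl_mea_layout` (default [mea_layout()]).
#' @param stim Stimulation schedule: data frame with columns `time` (s, within
#'   the window), `side` (`"LEFT"`/`"RIGHT"`) and `count` (signals delivered);
#'   `NULL` for no stimulation.
#' @param t0 Window start time in seconds.
#' @param duration Window length in seconds. Default 3.
#' @param seed Seed; defaults to `cfg$seed`. `NULL` uses (and advances) the
#'   current RNG stream.
#' @return An `nl_window`: list with `t0`, `duration`, `sample_rate`,
#'   `samples` (60 x n matrix) and `truth` (data frame `channel`, `time`).
#' @export
simulate_window <- function(cfg, layout = mea_layout(), stim = NULL,
                            t0 = 0, duration = 3, seed = cfg$seed) {
  stopifnot(inherits(cfg, "nl_network_config"),
            inherits(layout, "nl_mea_layout"))
  stim <- as_stim_frame(stim)
  if (nrow(stim) && (any(stim$time < t0) || any(stim$time >= t0 + duration)))
    stop_cfg("stimulation times must lie within [t0, t0 + duration)")
  n <- round(duration * cfg$sample_rate)
  eval_with_seed(seed, function() {
    samples <- matrix(stats::rnorm(60L * n, sd = cfg$noise_sd), nrow = 60L)
    out <- inject_spikes(cfg, layout, stim, t0, t0 + duration, samples)
    structure(list(t0 = t0, duration = duration,
                   sample_rate = cfg$sample_rate,
                   samples = out$samples, truth = out$truth),
              class = "nl_window")
  })
}

#' Write a voltage window or its ground-truth spikes as CSV
#'
#' `write_window_csv()` writes long-format samples (`channel`, `sample_index`,
#' `value`); `write_truth_csv()` writes the injected spike log (`channel`,
#' `time`).
#'
#' @param window An `nl_window`.
#' @param path File path.
#' @export
write_window_csv <- function(window, path) {
  stopifnot(inherits(window, "nl_window"))
  n <- ncol(window$samples)
  utils::write.csv(
    data.frame(channel = rep(1:60, each = n),
               sample_index = rep(seq_len(n), times = 60),
               value = as.vector(t(window$samples))),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_csv
#' @export
write_truth_csv <- function(window, path) {
  utils::write.csv(window$truth, path, row.names = FALSE)
  invisible(path)
}
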
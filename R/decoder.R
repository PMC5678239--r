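#' Per-channel mean and standard deviation of a voltage window
#'
#' @param window An `nl_window`.
#' @return Data frame with columns `channel`, `mean`, `sd`.
#' @export
channel_stats <- function(window) {
  stopifnot(inherits(window, "nl_window"))
  x <- window$samples
  n <- ncol(x)
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (n - 1))
  data.frame(channel = seq_len(nrow(x)), mean = m, sd = s)
}

# Greedy refractory thinning of sorted crossing sample indices.
thin_refractory <- function(idx, gap_samples) {
  if (length(idx) <= 1) return(idx)
  keep <- logical(length(idx))
  last <- -Inf
  for (i in seq_along(idx)) {
    if (idx[i] - last >= gap_samples) {
      keep[i] <- TRUE
      last <- idx[i]
    }
  }
  idx[keep]
}

#' Detect spikes by threshold crossing
#'
#' A spike ("signal") is a sample whose deviation from the channel mean
#' exceeds `k_sd` times the channel standard deviation. Statistics default to
#' the window's own mean/SD per channel; pass `stats` to use statistics from
#' another (e.g. the previously completed) window. Consecutive crossings
#' closer than the refractory gap are merged so one deflection yields one
#' event. Channels with zero variance yield no events.
#'
#' @param window An `nl_window` (any duration).
#' @param k_sd Threshold multiplier. Default 3.
#' @param refractory Minimum gap between events on one channel, seconds.
#' @param stats Optional data frame (`channel`, `mean`, `sd`) to use instead
#'   of the window's own statistics.
#' @param polarity `"both"` (default) uses the absolute deviation; `"positive"`
#'   counts only upward crossings.
#' @return An `nl_spikes` data frame with columns `channel`, `time` (s),
#'   ordered by time.
#' @export
detect_spikes <- function(window, k_sd = 3, refractory = 0.002,
                          stats = NULL, polarity = c("both", "positive")) {
  stopifnot(inherits(window, "nl_window"))
  polarity <- match.arg(polarity)
  if (is.null(stats)) stats <- channel_stats(window)
  dev <- window$samples - stats$mean
  if (polarity == "both") dev <- abs(dev)
  thr <- k_sd * stats$sd
  gap <- max(1, round(refractory * window$sample_rate))
  ch_out <- integer(0); t_out <- numeric(0)
  for (ch in seq_len(nrow(window$samples))) {
    if (stats$sd[ch] <= 0) next
    idx <- which(dev[ch, ] > thr[ch])
    idx <- thin_refractory(idx, gap)
    if (length(idx)) {
      ch_out <- c(ch_out, rep.int(ch, length(idx)))
      t_out <- c(t_out, window$t0 + (idx - 1) / window$sample_rate)
    }
  }
  ord <- order(t_out, ch_out)
  out <- data.frame(channel = ch_out[ord], time = t_out[ord])
  class(out) <- c("nl_spikes", "data.frame")
  out
}

#' Initialize the 60-element activation state
#'
#' The activation vector is a per-channel leaky spike count: between updates
#' every element decays as `A_n(t_i) = A_n(t_{i-1}) * exp(-beta * (t_i -
#' t_{i-1}))`, and each detected spike increments its channel's element by 1
#' at the spike time. All elements start at zero.
#'
#' @param n_channels Number of channels. Default 60.
#' @param beta Decay constant in 1/s (>= 0). Default 5 (time constant equal to
#'   the 0.2-s decision period).
#' @param t0 Initial time in seconds.
#' @return An `nl_activation`: list with `A`, `time`, `beta`.
#' @export
activation_state <- function(n_channels = 60, beta = 5, t0 = 0) {
  if (beta < 0) stop_cfg("beta must be >= 0")
  structure(list(A = numeric(n_channels), time = t0, beta = beta),
            class = "nl_activation")
}

#' Update the activation vector with a batch of spike events
#'
#' Events are processed in time order: the whole vector is decayed to each
#' event's time and the event's channel incremented by 1, then the vector is
#' decayed to `t`. This makes the recursive update exactly equivalent to the
#' closed form `A_n(t) = sum_k exp(-beta * (t - t_k))` over the channel's past
#' events. A bare integer vector of channels is treated as events all
#' occurring at `t`.
#'
#' @param state An `nl_activation`.
#' @param events An `nl_spikes` data frame (`channel`, `time`) with times in
#'   `[state$time, t]`, or an integer vector of channels.
#' @param t New time in seconds; must be `>= state$time`.
#' @return The updated `nl_activation`.
#' @export
update_activation <- function(state, events, t) {
  stopifnot(inherits(state, "nl_activation"))
  if (t < state$time)
    stop_cfg("t must be >= the state's last update time")
  if (!is.data.frame(events)) {
    events <- data.frame(channel = as.integer(events),
                         time = rep(t, length(events)))
  }
  A <- state$A
  cur <- state$time
  if (nrow(events)) {
    if (any(events$time < state$time - 1e-12) || any(events$time > t + 1e-12))
      stop_cfg("event times must lie within [state time, t]")
    if (any(events$channel < 1 | events$channel > length(A)))
      stop_cfg("event channel out of range")
    events <- events[order(events$time), , drop = FALSE]
    for (u in unique(events$time)) {
      A <- A * exp(-state$beta * max(0, u - cur))
      cur <- u
      A <- A + tabulate(events$channel[events$time == u], nbins = length(A))
    }
  }
  A <- A * exp(-state$beta * max(0, t - cur))
  structure(list(A = A, time = t, beta = state$beta),
            class = "nl_activation")
}

#' Fixed left/right reference activation vectors
#'
#' The templates encode left- or right-dominant network activity: `L` holds
#' `amplitude` on every LEFT-hemisphere channel and 0 elsewhere; `R` is the
#' mirror image. A decision is emitted only when the current activation vector
#' lies within Euclidean distance `delta` of the nearer template and the two
#' distances differ by more than `tie_margin`; otherwise the decoder reports
#' STOP. `delta = Inf` disables the proximity gate so only the winner margin
#' decides; `tie_margin` suppresses commands driven by symmetric spontaneous
#' activity (see [calibrate_tie_margin()]).
#'
#' @param layout An `nl_mea_layout`.
#' @param amplitude Per-channel template value `a` (> 0); see
#'   [calibrate_reference_amplitude()].
#' @param delta Acceptance radius (> 0, may be `Inf`).
#' @param tie_margin Minimum distance difference to declare a winner (>= 0).
#' @return An `nl_refs`: list with `L`, `R`, `delta`, `tie_margin`.
#' @export
reference_vectors <- function(layout = mea_layout(), amplitude = 9.5,
                              delta = Inf, tie_margin = 2) {
  stopifnot(inherits(layout, "nl_mea_layout"))
  if (amplitude <= 0) stop_cfg("amplitude must be positive (L must differ from R)")
  if (delta <= 0) stop_cfg("delta must be positive")
  if (tie_margin < 0) stop_cfg("tie_margin must be >= 0")
  n <- nrow(layout)
  L <- numeric(n); R <- numeric(n)
  L[hemisphere_channels(layout, "LEFT")] <- amplitude
  R[hemisphere_channels(layout, "RIGHT")] <- amplitude
  structure(list(L = L, R = R, delta = delta, tie_margin = tie_margin),
            class = "nl_refs")
}

#' Calibrate the reference amplitude from sustained stimulation
#'
#' Closed-form steady state of the leaky activation under sustained drive:
#' with `signals_per_s` stimulation signals per second, the pending-signal
#' count is `signals_per_s * evoked_duration`, the per-channel evoked rate is
#' `evoked_rate_gain` times that, and the steady-state activation sampled at
#' the decision period is `rate * period / (1 - exp(-beta * period))`
#' (assuming near-complete spike detection). This is the mean per-channel
#' activation the templates should reflect.
#'
#' @param cfg An `nl_network_config`.
#' @param signals_per_s Sustained stimulation rate the templates represent.
#'   Default 60/s (the drive produced by a tracking error of about one
#'   0.25-inch tolerance unit under the default scene and frame rate).
#' @param beta Activation decay constant, 1/s.
#' @param decision_period Decision period in seconds.
#' @return The calibrated amplitude `a` (scalar).
#' @export
calibrate_reference_amplitude <- function(cfg = network_config(),
                                          signals_per_s = 60,
                                          beta = 5, decision_period = 0.2) {
  pending <- signals_per_s * cfg$evoked_duration
  rate <- cfg$evoked_rate_gain * pending
  rate * decision_period / (1 - exp(-beta * decision_period))
}

#' Calibrate the tie margin from spontaneous activity
#'
#' Simulates unstimulated windows under `cfg`, runs the decoder at the
#' decision cadence, and returns `k_sd` times the standard deviation of
#' `d_L - d_R` across decisions. Using this as `tie_margin` makes commands
#' driven purely by symmetric spontaneous activity rare, while genuine evoked
#' asymmetries (orders of magnitude larger) still pass.
#'
#' @param cfg An `nl_network_config`.
#' @param refs An `nl_refs`.
#' @param layout An `nl_mea_layout`.
#' @param n_windows Number of 3-s spontaneous windows to simulate.
#' @param beta,decision_period Decoder parameters.
#' @param k_sd Multiplier on the observed SD. Default 3.
#' @param seed RNG seed.
#' @return The calibrated tie margin (scalar).
#' @export
calibrate_tie_margin <- function(cfg = network_config(),
                                 refs = reference_vectors(),
                                 layout = mea_layout(), n_windows = 10,
                                 beta = 5, decision_period = 0.2,
                                 k_sd = 3, seed = 1) {
  diffs <- eval_with_seed(seed, function() {
    state <- activation_state(nrow(layout), beta = beta, t0 = 0)
    out <- numeric(0)
    for (w in seq_len(n_windows)) {
      win <- simulate_window(cfg, layout, t0 = (w - 1) * 3, seed = NULL)
      dec <- decode_window(win, refs, state = state,
                           decision_period = decision_period)
      state <- dec$state
      out <- c(out, dec$decisions$d_L - dec$decisions$d_R)
    }
    out
  })
  k_sd * stats::sd(diffs)
}

#' Classify the activation vector into a motion command
#'
#' Computes the 60-dimensional Euclidean distances `d_L = ||A - L||` and
#' `d_R = ||A - R||`. If the nearer template is within `delta` and the
#' distances differ by more than `tie_margin`, the winner's motion command is
#' emitted under the contralateral mapping (right-dominant activity, i.e.
#' `d_R < d_L`, moves the arm LEFT, and vice versa); otherwise STOP.
#'
#' @param state An `nl_activation`.
#' @param refs An `nl_refs`.
#' @return List with `command` (`"MOVE_LEFT"`, `"MOVE_RIGHT"` or `"STOP"`),
#'   `d_L` and `d_R`.
#' @export
classify_activation <- function(state, refs) {
  stopifnot(inherits(state, "nl_activation"), inherits(refs, "nl_refs"))
  if (isTRUE(all.equal(refs$L, refs$R)))
    stop_cfg("reference vectors L and R must differ")
  d_L <- sqrt(sum((state$A - refs$L)^2))
  d_R <- sqrt(sum((state$A - refs$R)^2))
  command <- "STOP"
  if (min(d_L, d_R) <= refs$delta && abs(d_L - d_R) > refs$tie_margin) {
    command <- if (d_R < d_L) "MOVE_LEFT" else "MOVE_RIGHT"
  }
  list(command = command, d_L = d_L, d_R = d_R)
}

#' Decode a full recording window into motion decisions
#'
#' Detects spikes over the window (with the window's own channel statistics,
#' or `stats` if given), then walks the decision grid: every
#' `decision_period` seconds the activation vector is updated with the spikes
#' since the previous decision (decayed to their exact times) and classified
#' against the templates. A 3-s window at the default 0.2-s period yields
#' exactly 15 decisions.
#'
#' @param window An `nl_window`.
#' @param refs An `nl_refs`.
#' @param state Optional `nl_activation` carried over from the previous
#'   window; a fresh zero state is created otherwise.
#' @param decision_period Seconds between decisions. Default 0.2.
#' @param stats Optional channel statistics passed to [detect_spikes()].
#' @param ... Further arguments to [detect_spikes()].
#' @return List with `decisions` (data frame `t`, `d_L`, `d_R`, `command`,
#'   `n_events`) and the final `state`.
#' @export
decode_window <- function(window, refs, state = NULL, decision_period = 0.2,
                          stats = NULL, ...) {
  stopifnot(inherits(window, "nl_window"))
  if (is.null(state))
    state <- activation_state(nrow(window$samples), t0 = window$t0)
  events <- detect_spikes(window, stats = stats, ...)
  n_dec <- round(window$duration / decision_period)
  rows <- vector("list", n_dec)
  t_prev <- window$t0
  for (k in seq_len(n_dec)) {
    t_k <- window$t0 + k * decision_period
    batch <- events[events$time > t_prev - 1e-12 &
                      events$time <= t_k + 1e-12, , drop = FALSE]
    batch <- batch[batch$time >= state$time, , drop = FALSE]
    state <- update_activation(state, batch, t_k)
    cls <- classify_activation(state, refs)
    rows[[k]] <- data.frame(t = t_k, d_L = cls$d_L, d_R = cls$d_R,
                            command = cls$command, n_events = nrow(batch))
    t_prev <- t_k
  }
  list(decisions = do.call(rbind, rows), state = state)
}

#' Write spike events or decisions as CSV
#'
#' @param x A data frame (`nl_spikes` or a decision table).
#' @param path File path.
#' @export
write_events_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
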
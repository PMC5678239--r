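# Shared fixtures, built in code.

# A frame filled with one RGB color.
solid_frame <- function(width, height, rgb) {
  px <- array(0L, c(height, width, 3L))
  for (k in 1:3) px[, , k] <- as.integer(rgb[k])
  structure(list(width = width, height = height, pixels = px),
            class = "nl_frame")
}

# A voltage window built directly from a samples matrix.
manual_window <- function(samples, t0 = 0, sample_rate = 1000) {
  structure(list(t0 = t0, duration = ncol(samples) / sample_rate,
                 sample_rate = sample_rate, samples = samples,
                 truth = data.frame(channel = integer(0), time = numeric(0))),
            class = "nl_window")
}

# A mask built directly from a logical matrix.
manual_mask <- function(cells) {
  structure(list(width = ncol(cells), height = nrow(cells), cells = cells),
            class = "nl_mask")
}

# Noise-free-baseline network whose evoked responses dominate.
quiet_network <- function(...) {
  network_config(baseline_rate_left = 0, baseline_rate_right = 0,
                 evoked_rate_gain = 2, seed = 1, ...)
}

# Channel mirror map (row, col) -> (row, 9 - col) for symmetry checks.
mirror_map <- function(layout = mea_layout()) {
  m <- integer(nrow(layout))
  for (i in seq_len(nrow(layout))) {
    j <- which(layout$row == layout$row[i] & layout$col == 9 - layout$col[i])
    m[i] <- layout$channel[j]
  }
  m
}
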
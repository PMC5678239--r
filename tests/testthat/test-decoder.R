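test_that("threshold detection finds injected deflections and nothing in silence", {
  # an all-zero trace has no variance, hence no events
  expect_equal(nrow(detect_spikes(manual_window(matrix(0, 60, 3000)))), 0)
  # a 10-unit single-sample deflection on unit noise is always caught
  set.seed(21)
  for (i in 1:10) {
    x <- matrix(stats::rnorm(3 * 3000), 3, 3000)
    x[2, 1500] <- x[2, 1500] + 10
    ev <- detect_spikes(manual_window(x))
    hit <- ev[ev$channel == 2 & abs(ev$time - 1.499) < 1.5e-3, ]
    expect_gte(nrow(hit), 1)
  }
})

test_that("detection recovers >=95% of simulated ground-truth spikes", {
  stim <- data.frame(time = 0.2, side = "RIGHT", count = 8)
  cfg <- network_config(baseline_rate_left = 1, baseline_rate_right = 1,
                        evoked_rate_gain = 2, spike_amplitude = 6,
                        noise_sd = 1)
  w <- simulate_window(cfg, stim = stim, seed = 22)
  ev <- detect_spikes(w)
  matched <- vapply(seq_len(nrow(w$truth)), function(i) {
    any(ev$channel == w$truth$channel[i] &
          abs(ev$time - w$truth$time[i]) <= 1.5e-3)
  }, logical(1))
  expect_gte(mean(matched), 0.95)
})

test_that("activation decays exponentially and increments per event", {
  st <- activation_state(beta = 5)
  st$A[1] <- 1
  out <- update_activation(st, data.frame(channel = integer(0),
                                          time = numeric(0)), 0.2)
  expect_equal(out$A[1], exp(-1))  # beta * dt = 1
  # beta = 0: no decay for any interval
  st0 <- activation_state(beta = 0); st0$A[3] <- 2.5
  expect_equal(update_activation(st0, integer(0), 100)$A[3], 2.5)
  # one event on channel 7 from a fresh state
  fresh <- update_activation(activation_state(), 7L, 0)
  expect_equal(fresh$A[7], 1)
  expect_equal(sum(fresh$A), 1)
  # temporal ordering is enforced
  st2 <- update_activation(activation_state(), integer(0), 1)
  expect_error(update_activation(st2, integer(0), 0.5), "last update")
})

test_that("recursive activation equals the closed-form sum of decayed events", {
  set.seed(23)
  for (rep in 1:20) {
    beta <- stats::runif(1, 0.5, 10)
    n_ev <- sample(50:300, 1)
    times <- sort(stats::runif(n_ev, 0, 5))
    chans <- sample(1:60, n_ev, replace = TRUE)
    t_end <- 5.5
    # recursive path, events delivered in irregular batches
    st <- activation_state(beta = beta)
    cuts <- sort(c(0, stats::runif(7, 0, t_end), t_end))
    for (k in seq_len(length(cuts) - 1)) {
      sel <- times > cuts[k] & times <= cuts[k + 1]
      st <- update_activation(st, data.frame(channel = chans[sel],
                                             time = times[sel]),
                              cuts[k + 1])
    }
    # brute-force closed form
    oracle <- vapply(1:60, function(ch) {
      sum(exp(-beta * (t_end - times[chans == ch])))
    }, numeric(1))
    expect_lt(max(abs(st$A - oracle)), 1e-9)
    expect_true(all(st$A >= 0))
  }
})

test_that("classification picks the nearer template within gate and margin", {
  refs <- reference_vectors(amplitude = 2, delta = 100, tie_margin = 1e-6)
  st <- activation_state()
  st$A <- refs$L
  # L-dominant activity drives the arm right (contralateral mapping)
  out <- classify_activation(st, refs)
  expect_equal(out$command, "MOVE_RIGHT")
  expect_equal(out$d_L, 0)
  st$A <- refs$R
  expect_equal(classify_activation(st, refs)$command, "MOVE_LEFT")
  # equidistant vector: STOP by the tie rule
  st$A <- rep(1, 60)
  expect_equal(classify_activation(st, refs)$command, "STOP")
  # outside the acceptance radius: STOP
  tight <- reference_vectors(amplitude = 2, delta = 0.5, tie_margin = 1e-6)
  st$A <- rep(0, 60); st$A[1] <- 40
  expect_equal(classify_activation(st, tight)$command, "STOP")
})

test_that("mirroring channels and swapping templates flips every command", {
  refs <- reference_vectors(amplitude = 3, delta = Inf, tie_margin = 0.5)
  mm <- mirror_map()
  set.seed(24)
  for (rep in 1:20) {
    st <- activation_state()
    st$A <- stats::rpois(60, 1.5)
    cmd <- classify_activation(st, refs)$command
    stm <- activation_state()
    stm$A[mm] <- st$A
    cmdm <- classify_activation(stm, refs)$command
    expect_equal(cmdm, switch(cmd, MOVE_LEFT = "MOVE_RIGHT",
                              MOVE_RIGHT = "MOVE_LEFT", STOP = "STOP"))
  }
})

test_that("a 3-s window yields 15 decisions on the 0.2-s grid", {
  w <- simulate_window(quiet_network(),
                       stim = data.frame(time = 0.1, side = "LEFT", count = 5),
                       seed = 25)
  dec <- decode_window(w, reference_vectors())
  expect_equal(nrow(dec$decisions), 15)
  expect_equal(dec$decisions$t, seq(0.2, 3, by = 0.2))
  expect_equal(dec$state$time, 3)
})
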
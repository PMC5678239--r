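---
title: "Simulating a robot-embodied neuronal network: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a robot-embodied neuronal network: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(neuroloop)
```

## The system

An "embodied" cultured neuronal network is a closed-loop neurorobotic
preparation: a dissociated cortical culture grown on a multi-electrode array
(MEA) receives sensory input as electrical stimulation derived from a camera,
and its spiking output is decoded into motor commands for a robot arm that
carries the camera. The culture — segmented by a scalpel cut into two
independent "hemispheres" — acts as a minimal central nervous system: target
on the left stimulates the right hemisphere, right-hemisphere dominance moves
the arm left, and the loop closes when the arm centers the target in its view.

`neuroloop` simulates every stage of that loop so the complete system can be
run, perturbed and measured deterministically:

1. **Scene** (`scene_config`, `render_frame`, `sample_trajectory`): a solid
   red rectangular target at a controlled position against a mixed-color
   background containing red distractor pixels (a stand-in for non-target red
   objects such as the experimenter).
2. **Vision** (`rgb_to_hsv_planes`, `threshold_hue`, `strip_sums`,
   `stimulus_from_sums`): HSV conversion, hue thresholding to a binary mask,
   partition into five vertical strips, and quantization of the
   leftmost-3-minus-rightmost-3 white-pixel difference into stimulation
   signals — one digitized synaptic signal per full 500-pixel quantum,
   delivered contralaterally.
3. **Network** (`network_config`, `simulate_window`): a 60-channel surrogate
   for the culture — inhomogeneous Poisson spiking on Gaussian noise, with
   stimulation-evoked rate increases confined to the stimulated hemisphere.
4. **Decoder** (`detect_spikes`, `update_activation`, `classify_activation`):
   3×SD threshold crossing detection, a leaky 60-element activation vector
   $A_n(t_i) = A_n(t_{i-1})\,e^{-\beta (t_i - t_{i-1})}$ incremented by 1 per
   detected spike, and every 0.2 s a Euclidean-distance comparison against
   fixed left/right templates that emits `MOVE_LEFT`, `MOVE_RIGHT` or `STOP`.
5. **Arm** (`arm_state`, `apply_command`, `view_offset`, `homing_step`):
   constant-speed 1-D kinematics on a ±10″ rail, the camera rigidly centered
   on the arm, and a return-to-midpoint behavior after sustained target
   absence.
6. **Loop** (`loop_config`, `run_loop`, `run_tracking_experiment`): the shared
   clock, logging, and the within-0.25″ tracking statistic.

## Model assumptions

**The network is a rate model, not a biophysical one.** Channel $n$ fires as
a Poisson process with rate
$$\lambda_n(t) = \lambda^{\mathrm{base}}_{h(n)} + g \cdot P_{h(n)}(t),$$
where $h(n)$ is the channel's hemisphere, $g$ is the evoked gain
(spikes/s/channel per signal), and $P_h(t)$ counts stimulation signals
delivered to hemisphere $h$ within the preceding `evoked_duration` (1 s, the
duration of the digitized synaptic stimulus). Spikes are single-sample
deflections of amplitude 6 on unit Gaussian noise. There are no bursts, no
plasticity, no inter-hemisphere leakage (the segmentation is perfect by
construction) and zero stimulation latency. The decoder consumes only
threshold crossings, so this is the minimal structure that exercises it.

**Spontaneous activity is real and runs through the same decoder.** Baseline
firing (default 2 spikes/s/channel per side) is superimposed on evoked
activity, exactly as endogenous activity rides on stimulation in the culture.
Two consequences are reproduced: residual noise-driven commands jitter the
arm, and asymmetric baselines bias net arm movement toward the dominant
hemisphere's command direction (`spontaneous_bias_experiment`).

## Parameters, defaults and calibration

| parameter | default | units | rationale |
|---|---|---|---|
| frame size / target | 640×480 / 200×100 | px | target wider than one 128-px strip, so the strip imbalance grows by 2×height px per column of offset: the stimulus dead band is ≈0.04″ rather than the ≈0.8″ it would be for a sub-strip target |
| field of view | 10 | inches | covers the ±5″ target range; 64 px/inch |
| frame rate | 10 | frames/s | typical consumer-camera processing rate |
| quantum Q | 500 | px/signal | one synaptic signal per full 500-pixel difference |
| hue gate | tol 10°, S ≥ 0.5, V ≥ 0.3 | — | "full red" threshold with wrap-around; weakly saturated/dark pixels never count |
| baseline rate | 2 | spikes/s/channel | sparse spontaneous cortical-culture firing |
| evoked gain $g$ | 0.5 | spikes/s/channel/signal | keeps evoked rates ≤ ~50 spikes/s at ordinary tracking errors, where the same-window 3×SD threshold still sits below the spike amplitude; far larger gains inflate the window SD until detection collapses |
| spike amplitude / noise SD | 6 / 1 | trace units | 6σ events, ≥95% detectable at 3σ |
| $\beta$ | 5 | 1/s | decay time constant equal to the 0.2-s decision period |
| template amplitude $a$ | 9.5 | activation units | closed-form steady state under a sustained 60 signals/s drive (`calibrate_reference_amplitude`): $a = g P \Delta t/(1-e^{-\beta\Delta t})$ |
| acceptance radius $\delta$ | Inf | activation units | see below |
| tie margin | 2 | distance units | ≈2.3 SD of the spontaneous $d_L - d_R$ distribution (`calibrate_tie_margin`), so symmetric endogenous activity rarely commands motion while evoked asymmetries (an order of magnitude larger) always do |
| arm speed | 0.25 | inches/s | one 0.25″ tolerance unit per second; above the 0.167 in/s full-range sweep speed, and small enough that the ≈1-s evoked tail produces sub-tolerance turnaround overshoot |
| homing threshold H | 10 | frames | 1 s of sustained target absence before the arm returns to the midpoint |
| run length | 120 | s | default observation period; 40 recording windows, 600 decisions |

Three decoder defaults deserve their own justification, because the design
space was genuinely open:

- **$\delta$ (acceptance radius).** The classification rule is: command only
  if $\min(d_L, d_R) \le \delta$ and $|d_L - d_R| >$ tie margin, else STOP. A
  natural-looking choice $\delta = \lVert L \rVert_2$ makes the acceptance
  region a ball through the origin: any activation vector whose magnitude
  exceeds about twice the template amplitude is rejected, so under strong
  drive — exactly when the system should move — every decision becomes STOP
  and the loop freezes. We therefore disable the radius by default
  ($\delta = \infty$) and let the winner-plus-margin rule carry the STOP
  semantics; a finite $\delta$ remains available for experiments on
  saturation-gated behavior.
- **Tie margin.** With a near-zero margin, spontaneous activity alone emits a
  command nearly every tick and the arm performs a 0.05″-step random walk
  even with the target perfectly centered. The margin is the noise gate: set
  from the spontaneous $d_L - d_R$ spread, it makes a perfectly centered
  static target a true fixed point while leaving evoked asymmetries
  untouched. It deliberately does *not* eliminate all endogenous commands —
  the biological system's tracking was likewise contaminated by spontaneous
  activity.
- **Arm speed.** The loop's effective lag is dominated by the 1-s evoked
  window: after the target is centered, pending signals keep the driven
  hemisphere active for up to a second, so the arm overtravels by roughly
  speed × 1 s before commands flip or stop. At 0.25 in/s the overshoot stays
  within the 0.25″ tolerance band; at 1 in/s the loop limit-cycles with ≈1″
  amplitude and tracking accuracy collapses.

All calibrated constants were fixed once, from the closed-form calibrations
and short diagnostic simulations of the default configuration, and are
exposed in the configuration objects.

## Scheduling and numerical choices

- **Clock.** Frames every 0.1 s; a frame's stimulus is delivered to the
  network at the frame time; decisions on the 0.2-s grid; recording windows
  tile the run in 3-s blocks (15 decisions per window). Everything is driven
  from one integer step counter, so there is no floating-point drift.
- **Channel statistics are causal.** The standalone decoder
  (`detect_spikes`, `decode_window`) computes each channel's mean and SD from
  the window being decoded, matching the per-3-s-interval description. Inside
  the closed loop, a decision at 0.8 s cannot use statistics of a window that
  completes at 3 s, so `run_loop` uses the statistics of the last *completed*
  window and initializes them from a 3-s spontaneous calibration period
  simulated before the run. The two choices agree in distribution whenever
  activity is statistically stationary across adjacent windows.
- **Spike detection.** Crossings of ±3×SD about the window mean (absolute
  deviation by default; a positive-only switch exists), thinned by a 2-ms
  refractory gap so a single deflection yields a single event. Zero-variance
  channels yield no events by definition.
- **Activation updates are exact.** Events are folded in at their own times
  (decay to the event time, then increment), which makes the recursive state
  identical — to floating-point accumulation error, tested at 1e-9 — to the
  closed form $A_n(t) = \sum_k e^{-\beta (t - t_k)}$ over the channel's
  events.
- **Strip partition tie-break.** When the width is not divisible by 5, the
  wider strips are the leftmost ones — any fixed rule works, this one is
  documented and tested. Mirror antisymmetry of the stimulus is exact for
  widths divisible by 5.
- **Vision fast path.** Because the scene background is static and the
  target is an axis-aligned rectangle of exactly the thresholded hue, the
  white-pixel count per column is available in closed form;
  `run_loop(fast_vision = TRUE)` (the default) uses it, and the test suite
  verifies bit-identical stimulus streams against full per-frame
  rasterization through `rgb2hsv`.
- **Determinism.** A run is a pure function of its `loop_config`, including
  the seed; the scene's background field has its own seed and is drawn with
  RNG-state isolation so rendering never perturbs the simulation stream.

## What the generator does and does not emulate

The scene generator emulates a solid-hue target on a mixed background with
i.i.d. red distractor pixels and experimenter-controlled absence intervals.
It does not emulate lighting variation, camera optics, motion blur, target
shape variation, or spatially coherent distractor objects; the vision stage
is therefore tested on exactly the invariances it claims (hue gating,
strip counting, quantization), not on real-scene robustness.

The network surrogate emulates rate-level evoked responses with hemisphere
confinement and superimposed spontaneous firing. It does not emulate burst
structure, development, plasticity/LTP, stimulation-amplitude ceilings, or
culture-to-culture variability. Consequently the closed loop tracks *more*
cleanly than the biological preparation: the default configuration reaches a
within-0.25″ fraction of essentially 100% over 5 seeds, comfortably above —
but not comparable in spread to — the 68 ± 13% measured with living
networks. Passing the tracking benchmark here demonstrates that the
information flow and decoding pipeline are correct and well-calibrated, not
that biology behaves this well.

## Problem sizes used in the shipped checks

Tracking runs are 120 s (1 200 frames, 600 decisions, 40 windows) over the
±5″ triangle sweep, aggregated over 5 seeds; the deterministic convergence
check uses a noise-free-baseline network with a static target 3″ off-center
for 30 s; the target-removal scenario uses a 69-s run with a 20-s absence
window; the spontaneous-bias experiment uses 30-s runs over 10 seeds with a
3× left/right baseline asymmetry. These sizes give sub-percent Monte-Carlo
wobble in the reported fractions while keeping a full check of the package
in the low minutes.

## Known limitations

- 1-D kinematics only; no grasping, no vertical motion, no arm dynamics.
- The evoked-response magnitude per signal is not constrained by data; it is
  a calibrated free parameter (config-exposed), and conclusions should not
  be drawn from its absolute value.
- The decoder's L/R templates are idealized (uniform within a hemisphere);
  electrode-specific activity patterns are not modeled.
- Detection inside the loop inherits a one-window lag in its statistics;
  under abrupt rate changes the effective threshold adapts only at window
  boundaries.
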
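---
title: "Decoding hallux presses and timing an assistive hand: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding hallux presses and timing an assistive hand: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halluxgrip)
```

## The control problem

A commercial single-degree-of-freedom assistive hand is driven by two
digital lines: line A high with line B low opens the fingers, A low / B
high closes them, both low holds, and both high is undefined. The hand has
no position sensing — the only way to reach a target interfinger distance
(0 to 100 mm) is to hold the open line for the right amount of time. The
user's side of the interface is a force-sensing shoe insole: pressing it
deliberately with the big toe (hallux) produces a contact-force peak far
larger than anything walking produces in that channel, and pressing the
hallux is possible in any lower-limb state without disturbing balance.
`halluxgrip` implements, entirely in simulation, the chain that turns raw
insole samples into timed open/close commands:

1. **simulate** — multi-channel insole traces with gait loading, scheduled
   presses and sensor noise;
2. **filter** — recursive (moving) average plus a scalar Kalman filter;
3. **decode** — per-user threshold calibration and a crossing-halving
   press-count statistic per scan window;
4. **calibrate posture** — a polynomial map from interfinger distance to
   opening-time ratio, with data-driven order selection;
5. **control** — a five-level press-count-to-distance code, timed line
   commands, and a simulated plant that inverts the timing curve.

## Signal model and filtering

The raw channel value $y_k$ is baseline load plus gait loading plus press
bumps plus zero-mean Gaussian sensor noise, clipped at zero (the film
sensor cannot report negative force). The first smoothing stage is the
causal moving average over the most recent $N$ samples,

$$x_k = \frac{1}{N}\sum_{i=0}^{N-1} y_{k-i},$$

with $N$ conventionally in 40–60; the default is the midpoint, $N = 50$
(0.5 s at the default 100 Hz sampling rate). During warm-up ($k < N$) the
available prefix is averaged; no pre-stream data are fabricated. One
common statement of this recursion sums only $N-1$ lagged terms while
still dividing by $N$ and omits the current sample; we read that as a
typographical slip and implement the standard self-consistent windowed
mean including $y_k$.

The second stage is a scalar Kalman filter with state model
$x_k = F x_{k-1} + B u_{k-1} + w$, $z_k = H x_k + v$,
$\operatorname{var}(w) = Q$, $\operatorname{var}(v) = R$. The smoothed
force is modelled as a slowly drifting level, so $F = 1$, $B = 0$ (no
control input), $H = 1$. Defaults $Q = 10^{-2}$, $R = 1$ give a
steady-state gain near 0.1, i.e. a time constant of roughly ten samples.
$R$ is a package decision — only the process covariance has a conventional
value — and all parameters are user-settable through
`filter_params()`. The update step can only shrink the error covariance
($P' \le P^-$), which the test suite asserts as an invariant. The price of
the two-stage smoothing is delay (a fraction of a second); this is
acceptable in practice because users press ahead of the grasp they
intend.

## Press decoding

The threshold $t$ is personal: weight, foot shape and gait all move the
press-free force range, so $t$ is the maximum of a press-free filtered
segment (standing, sitting or walking) times a safety margin, default
1.1 — deliberately conservative, at the cost of requiring firm presses.
Within a scan window holding filtered values $a_1,\dots,a_N$, the press
count is

$$S = \frac{1}{2}\sum_{i=2}^{N} g\big((a_{i-1}-t)(a_i-t)\big), \qquad
g(x) = \begin{cases}1 & x < 0\\ 0 & x \ge 0,\end{cases}$$

half the number of strict threshold crossings: each deliberate press
crosses up once and down once. Samples exactly on the threshold do not
cross ($g(0) = 0$), so tangential touches never count. Three streaming
choices matter:

* **Window partition.** The stream is cut into consecutive,
  non-overlapping windows of `scan_time` seconds (default 1.5 s,
  adjustable per user against the latency/sensitivity trade-off). A press
  is attributed to the window containing its *falling* crossing, so a peak
  straddling a boundary is counted exactly once and summed window counts
  equal the total press count. A rising crossing with no fall by end of
  stream is not counted.
* **Warm-up exclusion.** The first $N$ samples are filter warm-up: the
  averaging queue is still filling, so early filtered values carry nearly
  raw sensor noise while the Kalman gain is still high. Crossings there
  are ignored; decoding starts once the queue is full.
* **Saturation.** Counts above the top code level saturate (four or more
  presses all command full open), applied at the mapping stage.

## Posture calibration

Timing is calibrated by opening the hand from fully closed for measured
times $t_i$ to distances $l_i$ and forming time ratios $d_i = t_i/t_A$,
where $t_A$ is the full-open time. The packaged dataset
(`hand_opening_times()`) has 23 pairs spanning 0–100 mm; note the ratio
0.25 at 0 mm — a quarter of the travel time is motor dead travel before
the fingers separate. $t_A$ is hardware- and voltage-dependent; the
package default is 2 s, a realistic travel time for this class of
gripper, and every dimensionless quantity (SSE, $R^2$, ratios) is
independent of it.

The model is a degree-$M$ polynomial fitted by least squares on an
explicit design matrix via QR (the normal-equations solution). For
conditioning, powers are taken of the centred-and-scaled abscissa
$\lambda = (l - \bar l)/s_l$; polynomial spaces are closed under affine
substitution, so SSE and $R^2$ are invariant to this transform (the test
suite cross-checks both against an independent orthogonal-polynomial
route). A point worth recording: the coefficients this package obtains on
the standardized abscissa, $(0.5976,\ 0.2644,\ -0.001985,\ 0.002019,\
0.01441)$, are exactly the coefficients sometimes quoted for this curve
"in mm" — quoted coefficients of that size cannot be raw-mm coefficients
($0.01441 \cdot 100^4 \gg 1$), and the match identifies the unstated
scaling as centre-and-scale.

```{r}
sel <- select_order(hand_opening_times(), max_order = 6)
sel$diagnostics
sel$order
```

The order is chosen by an elbow rule: stop at the last degree whose SSE
improved on its predecessor by at least 20% (relative); on the packaged
data the step from degree 4 to 5 improves SSE by only ~5%, so degree 4 is
chosen. A fit whose SSE is already negligible against the total sum of
squares short-circuits the rule (relative improvement is meaningless at
machine-zero SSE; this is what makes exact low-degree data select their
true degree). The 20% tolerance is a package default, settable by `tol`.

Two empirical properties of the degree-4 fit deserve honesty: its fitted
value at 100 mm is 0.9705, not 1 (the (100, 1) calibration row carries a
residual of about 0.03), and the curve has a ~0.002-deep dip below 3 mm —
a typical quartic end wiggle. The tests assert monotonicity from 3 mm up
and bound the dip rather than pretending the fit is globally monotone.
Predictions are clamped to $[0, 1]$, and targets outside 0–100 mm are
errors.

## Command planning and the simulated plant

Press counts map to targets through the five-level code (1 → 25 mm, 2 →
50 mm, 3 → 75 mm, ≥4 → 100 mm; zero presses while open → close; zero
while closed → no-op). The duration to move between two postures is the
difference of their opening times, quantised to a 10 ms command tick; the
direction picks the line pair, and the undefined high/high combination is
never emitted (asserted as a safety invariant over seeded scenario runs).
The simulated plant inverts the fitted curve: driving a line for duration
$\tau$ moves the mechanism $\tau/t_A$ along the time-ratio axis, and
openness is recovered by root-finding on the monotone span, clamped at
the end stops. Closing is assumed to traverse the same curve as opening —
the calibration data cover opening only, and a symmetric plant is the
parsimonious reading. With the 10 ms tick and $t_A = 2$ s the plan/plant
round trip lands within 2 mm of the commanded level; real hardware adds
backlash and load torque that this plant does not model, so millimetre
accuracies here say nothing about physical hands. Because the replayed
plant moves between windows instantaneously, no decoded window is ever
dropped while "the hand is moving" — the queue-not-drop semantics are
satisfied trivially in simulation.

## What the simulator does and does not emulate

`generate_trace()` reproduces the *qualitative* structure that the method
relies on: per-step half-sine loading in heel/forefoot channels during
walking (one peak per step at the commanded cadence over the stance
fraction), smaller walking peaks in the toe channels, near-baseline toe
channels at rest, smooth raised-cosine press bumps whose amplitude
(default 2000 counts on the nominal 0–2500 scale) clearly exceeds walking
toe peaks (default 500), and additive Gaussian sensor noise (default
sd 30 counts) truncated at zero. Identical seeds give bitwise-identical
traces. It does **not** emulate biomechanics: no step-to-step amplitude
variability, no double-support timing, no weight shifts, no sensor drift,
hysteresis or creep in the film sensors. Passing decoder tests on these
traces therefore demonstrates the logic of the chain under its stated
assumptions, not field performance with human subjects.

Deliberate-press choreography in the scenario generators and recovery
study is a package choice: 0.25 s taps about 1.4 s apart with ±0.08 s
jitter — an unhurried deliberate cadence. The spacing respects the
filter's temporal resolution: with a 0.5 s averaging queue plus the
Kalman lag, taps need roughly half a second of clean gap to remain
separable; faster tapping merges peaks and undercounts. Correspondingly,
multi-press codes pair naturally with a longer scan window (the scan time
is explicitly a per-user tuning knob); the multi-press scenario tests use
a 4 s window.

## Problem sizes and reproducibility

The packaged studies use: 23 calibration pairs (fits are instantaneous);
10,000 random sequences for the press-statistic/brute-force agreement
check; 1,000 simulated trials (12.5 s standing traces at 100 Hz, 0–6
scheduled presses) for the recovery study, which decodes the scheduled
count exactly in ≥99% of trials under default noise; 500 noisy replicates
(σ = 0.005) for the refit study, whose mean SSE matches the classical
$(n - M - 1)\sigma^2$ residual-degrees-of-freedom identity within a few
percent; and 200 seeded scenario replays for the safety and level-accuracy
invariants. All randomness flows from explicit seeds;
`scripts/acceptance.R` recomputes every headline number from scratch at a
caller-chosen seed.

## Known limitations

* Human-subject recognition and task-completion accuracies cannot be
  reproduced in simulation and are out of scope; the recovery study is a
  property check of the decoding chain, not a claim about users.
* The little-toe channel is simulated but not decoded (the hallux is the
  chosen control site); bimanual coordination is out of scope.
* The Kalman filter is scalar by design; richer plant dynamics or adaptive
  noise estimation are deliberately excluded.
* Preemption is unmodelled: the simulated plant completes each command
  between windows, so mid-motion presses never arise. On hardware this
  choice (abort vs. queue) would need an explicit decision.
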
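---
title: "Methods: the bcloop biocybernetic loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the bcloop biocybernetic loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcloop)
```

## The loop

`bcloop` closes a biocybernetic control loop around a headless Tetris game.
Cognitive load, indexed by normalized upper-alpha (10.5–13 Hz) band power at
parietal sites, drives one-step changes of the game's gravity interval; a
secondary affective signal — facial-expression valence — continuously
re-tunes the decision thresholds. The working assumption is the classic
inverted mapping between parietal alpha and engagement: sustained high alpha
relative to a person's own neutral baseline reads as disengagement/boredom
under excessive demand, so the game slows; a sustained two-fold drop reads
as the opposite, so it speeds up. The valence signal is read as an online
verdict on each adaptation: if the user's expressed affect falls right after
a speed change, that adaptation (and the threshold that triggered it) was
wrong for them.

One pacing cycle (10 s) proceeds as:

1. average the alpha ratio over the preceding 5 s (artifact epochs
   excluded);
2. compare against `(lower, upper)`: mean ≥ upper → slow down one level;
   mean ≤ lower → speed up one level; otherwise no adaptation;
3. (dynamic condition) judge the previous adaptation by the mean valence in
   the 2 s after it minus the 2 s before; a negative delta loosens the
   threshold that was crossed by one step;
4. (dynamic condition) if no adaptation occurred but the epoch's valence
   delta is negative, tighten both thresholds by one step.

Pending judgments are always resolved before the next evaluation; with the
default pacing (10 s) and window (2 s) a judgment never overlaps the next
epoch, but configurations where it would are queued in order.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `pacing` | 10 | s | interval between controller evaluations |
| `alpha_window` | 5 | s | alpha averaging window before each evaluation |
| `valence_window` | 2 | s | pre/post windows judging an adaptation |
| `epoch_len` | 0.5 | s | alpha epoch length (2 Hz ratio stream) |
| `upper_threshold` | 2.0 | ratio | a 100% increase over baseline |
| `lower_threshold` | 0.5 | ratio | a two-fold decrease |
| `threshold_step` | 0.1 | ratio | movement per loosen/tighten update |
| `initial_speed_ms` | 400 | ms | starting gravity interval (level 12) |
| `min/max_speed_ms` | 100 / 1500 | ms | level 15 / level 1 bounds |
| `guard` | TRUE | — | clamp threshold updates to sane orderings |

Thresholds are stored in ratio units because that is what the normalized
pipeline emits; the literature often quotes them in fractional-change units
(`fractional = ratio − 1`, so the default upper threshold is "1" and one
loosening makes it "1.1"); `ratio_to_fractional()` converts. The step size
0.1 is anchored by that 1 → 1.1 update and used symmetrically for both
thresholds and both directions.

### Crossing strictness

The crossing test is inclusive: a change of 100% *or more* triggers, so with
baseline 4 the upper threshold is crossed at raw alpha exactly 8 and the
lower at exactly 2. Besides matching the worked arithmetic, inclusiveness is
load-bearing for the runaway analysis below: with strict inequalities a
lower-threshold crossing would require `mean < lower`, and since the ratio
is non-negative the lower threshold could never be driven below zero — the
documented pathology would be unreachable by construction.

### Guard semantics

Threshold updates are the loop's only self-modifying element and, unguarded,
they can run away: sustained dissatisfaction after lower-crossings walks the
lower threshold down in 0.1 steps through zero into values a non-negative
ratio can never reach, and sustained quiet dissatisfaction tightens the pair
until the lower threshold sits above the upper. Both behaviours are
reproducible here (see the acceptance suite) because they are part of what
the system *is*; `guard = TRUE` (the default for practical use) clamps
updates so `lower ≥ step` and `upper − lower ≥ 2·step` always hold.
Tightening under guard stops symmetrically around the current midpoint.
Updates are kept on the exact decimal step grid (rounded at 1e-10) so that
repeated ±0.1 moves cannot drift off comparison boundaries through float
accumulation.

## EEG pipeline choices

The preprocessing chain is causal throughout because this kind of loop runs
online: rational-rate resampling to 256 Hz, a 4th-order Butterworth
band-pass at 1–50 Hz, a biquad notch at 60 Hz with Q = 30, an optional
blink-removal stage, and common-average referencing. "Infinite impulse
response" pins down only the filter family; 4th-order Butterworth and a
Q = 30 biquad are the standard online choices. Blink removal by blind source
separation has no published algorithm or parameters in this design, so the
stage is pluggable and defaults to pass-through, with a simple
amplitude-threshold interpolator (`blink_interpolate()`) available; the
loop's correctness does not depend on it. The first 2 s of any filtered
stream are treated as IIR warm-up and flagged as artifact.

Artifact detection compares each 0.5 s window's channel covariance with an
online mean — the running arithmetic mean in the log-Euclidean domain — by
the affine-invariant Riemannian distance
`sqrt(sum(log^2 eigenvalues(A^{-1} B)))`. No flagging cut-off is prescribed
anywhere, so a robust default is used: a window is flagged when its distance
exceeds the running median plus 5 running MADs (configurable). Epochs are
half-open `[t, t + 0.5)`; a partial trailing epoch is discarded, which keeps
epochs aligned with the 10 s pacing grid (20 epochs per pacing cycle).
Artifact-flagged epochs are excluded from averages rather than interpolated
(the original handling is unstated; exclusion is the conservative choice).
P3 and P4 powers are averaged into a single scalar per epoch — the decision
rule consumes one alpha value and "both channels kept" does not say how they
were combined; averaging is the symmetric choice and the channel set is
configurable.

Degenerate inputs fail loudly: streams below 256 Hz, single-channel CAR,
missing P3/P4 labels, non-positive baselines, calibration segments under
60 s or fully artifact-flagged all raise errors rather than guessing.

## Valence pipeline choices

Valence is positive-emotion intensity minus the strongest negative-emotion
intensity, in [−1, 1] for intensities in [0, 1]. All windows are half-open
with the post window starting at the adaptation instant inclusive, so the
pre/post windows tile the timeline with no gap or overlap. A delta of
exactly zero counts as satisfied — the update rule fires only on strictly
negative deltas. An empty window (face not detected, stream gap) yields the
verdict `"unknown"` and leaves thresholds untouched: a no-op is the only
update that cannot be wrong. Whether the upstream software's "positive
emotion" is the single happy intensity or a composite is internal to that
software; `valence_ratio()` takes one designated positive entry (default
`happy`) and treats all others as negative.

## Game engine choices

The board is 10 × 20 with only lateral moves and rotations — deliberately no
soft or hard drop, so descent time is controlled entirely by the gravity
interval. Levels map as `speed_ms = 1600 − 100·level`. Mechanics the control design
leaves open are filled with the simplest deterministic choices: the 7 standard tetrominoes drawn uniformly by a self-contained LCG
(so the engine never touches R's global RNG), rotation within a fixed
bounding box with wall rejection and no kicks, no lock delay, at most one
action per engine call. After a death the board clears while level, speed
and cumulative score persist (scores and deaths are reported per condition,
cumulatively). The control condition's four-row counter is cumulative
(level-ups at every crossing of a multiple of 4) rather than resetting per
level — the alternative reading; the choice is isolated in
`progression_update()`.

## The simulated subject

The subject model exists to close the loop offline; it is a simulation
convenience, not an estimate of any human population.

* **Policy** — greedy one-piece placement minimizing a weighted (holes,
  aggregate height, bumpiness) cost with deterministic tie-breaks (fewer
  rotations, then leftmost); with probability `error_rate(level)` (logistic
  in `level − skill`) a uniformly random other placement is chosen. Actions
  are emitted no faster than `response_latency × speed_ms`, and an action
  currently infeasible (e.g. a rotation at spawn) is held and retried, not
  dropped.
* **Alpha** — `ratio = max(0, alpha_base + alpha_gain·(level − skill) +
  AR(1) noise)`, one value per 0.5 s epoch. AR(1) (coefficient 0.8) rather
  than white noise because band-power series are autocorrelated — this is
  what makes averaging over 5 s meaningful. With the defaults
  (base 1.0, gain 0.3, SD 0.4) long-run draws stay within [0, 7], emulating
  the observed dynamic range of the normalized pipeline.
* **Valence** — a Gaussian flow curve `v_max·exp(−(level − skill)²/(2w²))`
  plus white noise, evaluated on the level that was active
  `response_latency` seconds ago, clipped to [−1, 1]: moves toward skill
  raise the 2 s post-window mean, moves away lower it. Two adversarial
  modes support stress-testing: a deterministic declining ramp (negative
  deltas everywhere — drives tightening runaway) and an adaptation-averse
  mode (a 2.5 s valence drop after every adaptation, flat otherwise —
  drives loosening runaway).

The generator deliberately omits features of real data: no 1/f EEG
background or line noise in ratio mode (a separate raw-EEG mode,
`gen_raw_eeg()`, synthesizes an amplitude-modulated 11.75 Hz carrier in 1/f
noise to exercise the full DSP path), no blinks or electrode artifacts
beyond what the artifact tests inject, no learning or fatigue drift across
a session, and no strategic play beyond one-piece lookahead. Passing tests
therefore demonstrate the correctness and closed-loop behaviour of the
*controller* under controlled subject models — not that the controller
improves real users' experience, which remains an empirical question that
only human-subject studies can answer.

## Problem sizes

The test suite runs sessions of 60–900 simulated seconds (the full-length
900 s / 90-epoch session shape is exercised directly) and populations of six
heterogeneous subjects at 300 s each; DSP tests use 8–70 s streams at
256–500 Hz. The acceptance sweeps scan raw alpha in 1e-4 steps across six
baseline widths (240,001 grid points) and confirm each boundary through the
package's own epoch evaluation on both sides.

## Known limitations

* The loop consumes emotion-intensity or valence streams; facial action
  coding from video is out of scope, as are EEG acquisition and
  hardware/LSL ingestion (EDF/BDF/XDF readers are not provided).
* Full online blind source separation for blink removal is not implemented
  (pluggable stage, see above).
* The two-band (frontal theta + parietal alpha) boredom/overload rule found
  elsewhere in the literature is not used by this design and not
  implemented.
* Reinforcement-learning threshold policies are a natural extension but out
  of scope here.
* `avg_level` is computed from the per-pacing-epoch level (the level
  prevailing at each epoch start); in the adaptive conditions the level is
  constant within an epoch by construction, in the control condition
  within-epoch progression is additionally captured by the recorded
  per-epoch min/max, which is what the extreme-dwell counts use (a "10 s
  period at a speed" requires the whole epoch at that level). Dwell periods
  are counted in total, not consecutively.
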
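---
title: "Comparing periodic movements: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing periodic movements: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(movewarp)
```

## The problem and the model

A person learning a periodic motor skill — a dance step, a gait pattern, a
swim stroke — repeats one movement cycle many times. A wearable
accelerometer at a fixed body site turns each attempt into a time series.
`movewarp` answers two questions about a learner's recording relative to an
expert's: *is the movement the same?* and *if not, where in the cycle does
it differ?*

The recording is reduced to the acceleration magnitude
$v_t = \sqrt{x_t^2 + y_t^2 + z_t^2}$, which is invariant to how the sensor
was oriented on the body; this trades away directional information for
robustness to sloppy sensor placement, which is the realistic field
condition. The pipeline assumes:

* both recordings are in the same unit and were captured at the same
  sampling rate (checked; never silently converted — `convert_unit()` exists
  but must be called explicitly);
* the movement is genuinely periodic with a stable cycle length over the
  recording (the method estimates one period per recording, not a
  time-varying one);
* recordings are several cycles long (at least two, realistically ~20).

Everything downstream is index-based; the sampling rate is carried as
metadata only.

## Pipeline stages and their parameters

**Periodicity.** The Pearson-iteration profile
$P_k = \mathrm{cor}(v, \mathrm{rot}(v, k))$, $k = 1..n$, is a circular
autocorrelation; for a cyclic signal it peaks each time the rotation
completes a whole number of cycles. Maxima are local peaks with minimum
height 0.5 and minimum separation 3 shifts (`peak_params`); the height bound
keeps noise wiggles out, the separation bound keeps flat peak tops from
double-counting. The period is reported two ways: the raw median spacing of
the maxima, and spacing − 1, which is the convention the reference case
studies print (a 125-iteration spacing read as a 124-sample period). The
spacing − 1 value is used as the gate quantity and called the period
throughout the reports; the raw spacing is always available alongside. Both
recordings must have *exactly equal* integer periods to proceed — a strict
gate, on the grounds that a tempo mismatch is a different movement no matter
how similar the shapes.

The profile can be evaluated two ways, `method = "fft"` (default) and
`method = "direct"`. They are the same quantity: rotation preserves the mean
and variance, so the shift-and-correlate definition reduces to the circular
autocovariance, which one FFT pair evaluates at every lag. The test suite
cross-checks the two to 1e-9; the FFT form simply keeps ~3000-sample
profiles fast inside loops.

**Synchronization.** The learner's first cycle is rotated against the
expert's ($R_k = \mathrm{cor}(v', \mathrm{rot}(u', k))$, $k = 0..n'-1$) and
the best rotation is converted to a head-drop on the learner: discard
$(n' - k_{\max}) \bmod n'$ leading samples. The conversion matters: the
carousel rotation and the head-drop act in opposite directions, so dropping
$k_{\max}$ samples itself would *not* align an asymmetric cycle. The
round-trip property test (drop the estimated shift, check the whole-series
correlation rises) pins the direction. Ties take the smallest rotation;
a best correlation below 0.2 flags the report `low_confidence` but does not
abort — there is no natural hard threshold here, and the verdict criteria
downstream already punish misalignment. Both series then start at the raw
maximum of their first cycle (earliest sample on ties) and are truncated to
the common length.

**Conditioning.** Min–max normalization onto 0..10000 first, then a 5-point
moving-average filter, in that order (the order the decision pseudocode the
case studies were produced with applies; the reversed order changes results
only marginally but reproducibility demands picking the printed one). The
filter window is 5 samples — about 4 % of a cycle — and the output is
`n − 4` samples long; the window is user-overridable, with a warning for
even widths since they shift phase by half a sample. Normalization to a
0..10000 integer-ish scale rather than 0..1 only changes the units of the
cost matrix and of `diff_max`; the default thresholds assume this scale.
Constant input (a flat signal) is an error at this stage, not an `NA`:
nothing meaningful can be compared.

**Warping.** The analysis deliberately uses a *single* randomly chosen
cycle: over a whole recording the warping path always straightens onto the
ideal line and differences wash out. The cycle multiple `k` is drawn
uniformly from `1..floor(L/p) − 1` under the caller's seed (`window_k`
overrides the draw to reproduce a fixed window), and the window
`k·p .. k·p + p` (inclusive, `p + 1` samples) is cut from both conditioned
series. The cost matrix is `|u_j − v_i|` — absolute differences, since a
distance must be non-negative and a minimum search over signed differences
would chase the most negative value rather than the closest match. The
default path is the greedy adjacent-side walker (step to the cheapest of
right/diagonal/up; ties prefer diagonal, then right, then up, biasing toward
the ideal line; at the border the candidate set shrinks). The classical
dynamic-programming path (`path_method = "dp"`) is provided both as a
lower-bound oracle in the tests (dp cost ≤ greedy cost, always) and as a
more robust alternative; greedy stays the default because it is what
produced the reference case-study numbers.

**Verdict.** Least squares of path `j` on path `i` gives `y = m·x + b`; the
criteria are equal periods, `R² > 0.9`, and mean |fitted − ideal| `< 10`
(`r2_min`, `diff_max`, both configurable). The idealized rule (difference
exactly 0, R² exactly 1) only ever holds for identical input; the 0.9/10
thresholds are the operational rule the case studies apply.
`localize_discrepancy()` flags path points whose cost exceeds
`band_fraction = 0.25` of the windows' value spread and merges runs closer
than 5 samples; the fraction is a named parameter and this feedback
localization is an extension operationalizing a qualitative reading, not a
published formula.

## The synthetic generator

`signal_spec()` defaults describe the study conditions the pipeline targets:
124-sample cycles, 24 cycles (~3000 samples per recording), magnitudes on
the m/s²×100 scale (baseline 1000 ≈ gravity, amplitude 400), additive
Gaussian noise with sd 20 (5 % of amplitude). The `gait` waveform is one
sharp impact peak (Gaussian bump at phase 0.25, width 0.05) plus one broad
swing hump (phase 0.65, width 0.18), weighted 1.6:0.7 — a fixed, documented
template giving the asymmetric within-cycle structure a sine lacks, which
matters for testing synchronization (a sine's autocorrelation cannot
distinguish offsets from reflections).

`generate_pair()` fixes the perturbation severities once: phase offset of a
quarter cycle (tolerated — synchronization removes it), amplitude × 1.8
(tolerated — normalization removes it), tempo × 0.5 (rejected — the period
gate), and a shape distortion replacing the middle 40 % of every cycle with
its time-reverse scaled ×2 about the segment mean (rejected — the learner
starts and ends each cycle correctly but performs its middle wrong). The
200-pair benchmark is 100 tolerated pairs (none/phase/amplitude) and 100
rejected ones (50 tempo, 50 shape).

What the generator does *not* emulate: cycle-to-cycle variability in period
(real movers drift a few samples per cycle), non-Gaussian sensor noise and
clipping, slow baseline drift, and tri-axial structure (it synthesizes the
magnitude directly). Passing the synthetic suite therefore shows the
algorithm implements its definition and tolerates what it claims to
tolerate; it does not certify performance on recordings whose period
wobbles, which the strict integer period gate handles harshly.

## Numerical choices and degenerate inputs

* 0-based shifts internally; all reported sample indices are 1-based.
* Argmax/argmin ties always break toward the smallest index, everywhere.
* The profile entry at shift `n` equals 1 by construction and counts as a
  maximum when it clears the height bound (the interior peak finder cannot
  see boundary maxima).
* Period aggregation uses the *median* maxima spacing, resisting one
  spurious peak.
* Constant series are errors at correlation, synchronization and
  normalization; an all-zero-amplitude spec exists in the generator
  precisely to exercise those errors.
* Windows shorter than two cycles, shifts outside the series, and filter
  windows longer than the series are errors with stage-named messages.
* FFT and direct profiles agree to 1e-9 (asserted); profile values are
  clamped to [−1, 1] against round-off.

## Problem sizes in the tests

The suite and the acceptance script run entirely from generated signals at
the study scale: ~3000-sample recordings, 100-trial recovery checks, a
200-pair benchmark, 1000 random cost matrices for the path-optimality
bound, and exhaustive path enumeration up to 7×7. The whole suite completes
in a few minutes on one CPU.

## Known limitations

* **The greedy walker is not stable.** Its route is a chain of local
  decisions, so a small input change can reroute a long stretch of the
  path; R² can swing widely between nearly identical inputs. Measured
  consequence: on a 20-level ladder of growing mid-cycle distortion, the
  verdict can flip back from different to similar at intermediate levels
  (the strict monotonicity expectation in the acceptance suite fails for
  7/10 seeds; the DP path still dithers at the R² = 0.9 boundary for 2/10).
  What does hold, and is asserted: undistorted pairs always pass and
  strongly distorted pairs always fail. Users wanting stability should use
  `path_method = "dp"`; users wanting fidelity to the reference numbers
  should keep greedy.
* **One random cycle.** The verdict is a property of one cycle window; two
  runs with different seeds can disagree near the thresholds. Fixing
  `window_k` makes a run reproducible; aggregating over windows is out of
  scope by design.
* **Strict period gate.** Integer equality of estimated periods; estimation
  noise of ±1 sample on a noisy recording fails the gate. This is faithful
  to the decision rule the package implements.
* The discrepancy localization is a documented extension, not part of the
  published decision rule.
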
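---
title: "Differential inertial breathing monitoring: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential inertial breathing monitoring: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathband)
```

## The measurement principle

A chest-worn accelerometer sees three superimposed signals: gravity
(orientation), whole-body motion, and the small chest-wall modulation caused
by breathing. A second accelerometer on the back sees the first two but not
the third. Differencing the two *magnitudes*,

$$\Delta a(t) = \lVert \mathbf a_{\mathrm{front}}(t)\rVert -
               \lVert \hat{\mathbf a}_{\mathrm{back}}(t)\rVert,$$

cancels every component common to both sensors and leaves a signal whose
dominant content is respiration. Because the two sensors are read
sequentially on one I²C bus (back, front, back, …), the back value at the
front sample time is estimated as the mean of the bracketing back samples
(`estimate_back_at_front()`); for any component-wise linear signal this
estimate is exact, and for a band-limited signal the residual is bounded by
$(\Delta t^2/2)\,\max|\ddot m|$ with $\Delta t$ the half-sample offset.

Two consequences of using magnitudes are worth stating because they shape
both the simulator and the limits of the method:

* a **rigid rotation** of either sensor leaves its magnitude unchanged, so
  the alignment check (`alignment_check()`, mean $|\Delta a|$ during a still,
  breath-held interval) detects gain/offset imbalance and placement-induced
  signal differences, not pure rotation;
* the magnitude is **first-order sensitive** only to acceleration components
  parallel to the total (≈ gravity) vector. The simulator therefore places
  the quasi-static gravity projection on the chest-normal axis that carries
  the breathing modulation; with gravity orthogonal to it the modulation
  would enter only at second order and no magnitude-based device could see
  it.

## Signal chain

`run_pipeline()` composes, per recording:

1. `build_diff_signal()` — Δa per front sample, dropping unbracketed edge
   samples (counted in the run log);
2. `lowpass_filter()` — causal Butterworth low-pass, default cutoff 0.6 Hz
   (the respiratory band is roughly 0.2–0.6 Hz). The filter is applied
   sample-by-sample (IIR), exactly as streaming firmware would;
3. `dispersion_labels()` — the streaming smoothed z-score detector;
4. `collapse_runs()`, `debounce_exhalations()`, `update_cycle_times()`,
   `finalize_window()` — events, plausible TI/TE candidates, and the
   per-window summary.

### The dispersion (smoothed z-score) detector

For each new filtered sample the detector compares the deviation from the
moving mean of the last `lag` points of an internal history against
`threshold` moving standard deviations (population form, divide by `lag`).
Samples that exceed are labelled ±1 by sign and enter the history damped,
as `influence * x + (1 − influence) * previous`; others are labelled 0 and
enter unchanged. The damping keeps the moving statistics anchored to the
pre-peak baseline, so a sustained rise keeps labelling +1 until the signal
turns — on the differential breathing signal, +1 runs span inspiration and
a short −1 run marks the expiratory drop. Run onsets, not run lengths, are
the breath events.

Two numerical details:

* the moving statistics are maintained with O(1) running sums; the variance
  is clamped at zero before the square root to absorb rounding;
* the moving SD has a floor `min_sd`, default one LSB of a 16-bit ±2 g
  accelerometer ($2^{-14}$ g ≈ 61 µg). The z-score is scale-invariant, so
  without a floor the detector would label micro-g interpolation and
  quantisation residue during otherwise silent passages — deviations below
  the sensor's own resolution carry no information. Setting `min_sd = 0`
  restores the textbook behaviour (any nonzero deviation over a zero-SD
  window fires).

### Breath events, debounce, and window summaries

A −1 run onset is an exhalation candidate; it is accepted only if it falls
more than `t_min_peak` (preset 5: 1.0 s) after the previously *accepted*
exhalation — rejected peaks do not advance the reference time. Accepted
exhalations increment the breath counter NP. Candidate durations
TI = t(exhalation) − t(latest inhalation) and TE = t(inhalation) −
t(previous exhalation) are accumulated only inside plausibility bounds
(default [0.4, 8] s for both, covering roughly 4–40 breaths/min; the exact
pairing convention is a package choice — the event semantics admit several
and this one recovers the simulator's ground truth). At each `Tw` boundary
the window is closed: RR = NP·60/Tw, TI_med/TE_med are accumulator means,
IER their ratio, V = Vt·60/TI_med, and the whole tracker state — including
the debounce reference — is cleared, mirroring a firmware loop that resets
its variables per window. Empty accumulators yield `NA` (RR = 0 is
meaningful and reported as such).

### Tidal volume

Vt = 7 mL/kg of ideal body weight, with IBW = 50 kg (men) / 45.5 kg
(women) + 0.91·(height_cm − 152.4). Heights below ~102 cm (women) would
drive the linear formula negative; the package clamps at 0 with a warning.
V therefore inherits the IBW assumption and is an estimate of ventilatory
drive, not a spirometric measurement.

## Parameter presets

`load_preset(0:5)` returns the six firmware parameter sets explored during
optimisation (cutoff frequency, lag, threshold, influence, debounce time;
milliseconds converted to seconds once, at the configuration boundary).
Set 5 — 0.6 Hz, lag 60 samples, threshold 2.87 σ, influence 0.58, 1.0 s
debounce — is the default throughout.

The **filter order** is a package decision: the presets do not determine
it. The default is order 1. The reason is quantitative: at brisk breathing
(~24 breaths/min and above) a second-order 0.6 Hz filter attenuates the
expiratory transition so strongly that the detector misses a large fraction
of breaths (in simulation, half of them at 24 BrPM), while a first-order
roll-off keeps the transition detectable across the resting-to-brisk range.
The gentler slope admits more in-band noise, which costs occasional false
peaks at slow rates (see *Limitations*); the order is configurable
(`pipeline_config(filter_order = …)`) for users who prefer the opposite
trade-off.

## The synthetic-data generator

`simulate_dual_imu()` emulates the acquisition geometry: back samples at
$k/f_s$, front samples at $(k+\tfrac12)/f_s$ (the interleaved read order
with symmetric half-sample offsets), both streams passed through the IMU's
integrated 21 Hz low-pass and clipped to ±2 g.

**Breathing waveform.** Each cycle contributes a bipolar kernel: a rise
from 0 to +A over TI as $\sin(\pi u/2T_I)$ (brisk inspiratory onset,
plateau at end-inspiration), then a fast elastic recoil plunging through
baseline to −A/2 over the first 0.2·TE, a smooth return to 0 by 0.45·TE,
and an exact end-expiratory pause for the remainder. The shape follows the
physiology of resting breathing — active inspiration, passive recoil, then
a pause — and reproduces the morphology that magnitude-differencing
devices record: positive acceleration while the chest expands, a steep
negative excursion at exhalation onset. Those onset-locked transitions are
what the dispersion detector keys on; a unipolar smooth envelope (rise to
+A and back to 0, no undershoot, no pause) is *undetectable in principle*
at the preset thresholds, because the z-score is amplitude-invariant and a
smooth envelope never deviates from its own moving statistics by more than
about 3 σ, and its return *to* baseline never produces the below-baseline
excursion that the −1 label requires. The shape constants (undershoot 0.5,
plunge 0.2·TE, recovery end 0.45·TE) are fixed in code.

**Defaults** (chosen once, on plausibility for a torso-worn MEMS device):
breathing modulation 20 mg with TI = 1.5 s, TE = 2.0 s (≈17 breaths/min)
and 10 % cycle-to-cycle lognormal variability; cardiac micro-artifact 3 mg
as a 10 Hz wiggle gated at 1.2 Hz (front sensor only); white sensor noise
3 mg per axis (≈1.8 mg RMS after the 21 Hz prefilter, matching a MEMS
noise floor of ~400 µg/√Hz); postural sway 5 mg seated / 10 mg standing
(band-limited < 2 Hz, common to both sensors); walking as the first three
harmonics of a 1.8 Hz step frequency at 0.3 g fundamental plus 10 % sway.
A `motion_mismatch` fraction (default 2 %) of the motion is not common to
the sensors, emulating imperfect placement. The ground truth attributes a
breath to the half-open 30 s window containing its exhalation onset
(`t_start + TI`), the instant the debounced detector targets.

**What the generator does not emulate:** posture transitions, sensor bias
drift, breath-holds mixed with motion, talking/coughing, and the
site-dependent motion differences of a real torso (motion mismatch is a
scalar gain). Passing recovery tests on these simulations therefore
demonstrates the correctness and self-consistency of the processing chain
under the stated signal model, not clinical accuracy on human subjects.

## Validation protocol

The test suite checks each stage against independent oracles: closed-form
Butterworth magnitudes, a from-scratch batch re-implementation of the
detector recurrence, naive-loop implementations of Pearson/Bland–Altman/MAE
on random instances, brute-force enumeration of ground-truth breath counts,
and hand-computed values for the formula constants. End-to-end, a noiseless
seated simulation must recover every per-window breath count exactly and
the mean TI/TE within one sample period plus the filter group delay; under
default walking artifacts the mean absolute RR error over 20 windows must
stay within 2 breaths/min (one debounce quantum).

`scripts/acceptance.R` additionally characterises the device the way a
validation study would: per posture (seated, standing, walking), three
210 s recordings at ≈17, 20 and 24 breaths/min, with Pearson r, MD, LoA
and MAE of the device RR against the true per-window rate pooled over 21
windows. The problem sizes (10 + 63 windows of 30 s, one CPU, a few
seconds total) were chosen to keep the protocol quick while giving each
statistic a meaningful n.

## Limitations

* **Slow breathing / apnoea.** Below ~15 breaths/min the end-expiratory
  pause grows long, and band-limited sensor noise occasionally crosses the
  detector threshold inside it; surviving false peaks overestimate RR by
  roughly one breath per window under the default noise floor. A true
  apnoea (flat Δa with noise) produces spurious low-rate counts rather
  than zero — the z-score detector has no notion of absolute amplitude.
  Only a fully quiet record yields NP = 0 exactly.
* **Brisk breathing.** Above ~28 breaths/min the pause shrinks below the
  detector's lag window (0.6 s at 100 Hz) and sensitivity drops sharply;
  breaths are missed wholesale regardless of filter order. The usable
  range of the default configuration is roughly 15–28 breaths/min.
* **IER and V.** Both are ratios of quantities each carrying detection
  delay differences; their relative errors are correspondingly larger than
  RR's, and V additionally inherits the ideal-body-weight tidal-volume
  assumption, which is not validated against spirometry here.
* **r on near-constant references.** With a steady breathing rate the
  reference RR has almost no variance and the Pearson coefficient is
  uninformative; MD/LoA/MAE are the meaningful statistics there. The
  acceptance protocol varies the rate across recordings for this reason.
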
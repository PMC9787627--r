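# breathband

Breathing parameters from a dual-IMU chest band, by differential inertial
sensing.

`breathband` implements, as reusable R functions plus a small CLI, the full
processing chain of a wearable respiratory monitor built from two triaxial
accelerometers: one on the chest, one on the back. The back sensor sees the
body's motion but not the breathing movement, so the difference of the two
acceleration magnitudes,

```
Δa(t) = |a_front(t)| − |â_back(t)|,
```

cancels common-mode motion artifacts and retains the chest-wall modulation.
`â_back` is the mean of the two back samples bracketing each front sample
(the streams are read in interleaved back→front→back order). Δa is low-pass
filtered with a causal Butterworth filter (default 0.6 Hz, the respiratory
band) and segmented by a streaming dispersion (smoothed z-score) peak
detector with parameters *lag*, *threshold* and *influence*: samples more
than `threshold` moving standard deviations above/below the moving mean of
the last `lag` influence-damped samples are labelled +1 (inhalation) / −1
(exhalation). Debounced exhalation events (minimum spacing `t_min`) are
counted per observation window of length `Tw` (default 30 s), giving

- **RR** = NP · 60 / Tw (breaths per minute),
- **TI_med**, **TE_med**: mean inhalation / exhalation durations from the
  event intervals, filtered by physiological plausibility bounds,
- **IER** = TI_med / TE_med,
- **V** = Vt · 60 / TI_med (L/min), with tidal volume Vt = 7 mL per kg of
  ideal body weight (Devine-style: 50 kg [men] / 45.5 kg [women]
  + 0.91 · (height_cm − 152.4)).

Because no public recordings exist for this device class, the package ships
a seeded synthetic dual-IMU generator (`simulate_dual_imu()`) that emulates
the chest/back geometry — gravity, a bipolar breathing waveform with fast
expiratory recoil, cardiac micro-artifact, common-mode body motion (postural
sway or gait harmonics), and sensor noise — together with per-window ground
truth for parameter-recovery testing. Agreement between a device series and
a reference is quantified exactly as wearable-validation studies do:
Pearson r, Bland–Altman mean difference (MD) and limits of agreement
(LoA = MD ± 1.96·SD), and mean absolute error (relative % and absolute).

## Worked example

```r
library(breathband)

spec    <- scenario_spec("seated", duration = 300, seed = 7)
rec     <- simulate_dual_imu(spec)                  # front + back streams + truth
subject <- subject_profile("male", height_cm = 182, weight_kg = 78)
res     <- run_pipeline(rec$front, rec$back, load_preset(5), subject)
print(res)
```

```
<pipeline_result> 10 windows
   window_start NP RR_brpm TI_med_s TE_med_s    IER V_lpm
1             0  9      18    1.443    1.606 0.8982 22.40
2            30  9      18    1.423    1.897 0.7500 22.71
3            60  8      16    1.576    1.773 0.8886 20.51
...
10          270 10      20    1.442    1.582 0.9113 22.41
```

Each row is one 30 s window: `NP` debounced breaths, respiration rate in
breaths/minute, mean inhalation/exhalation times in seconds, their ratio,
and the estimated flow rate in litres/minute (the subject's ideal body
weight of 76.936 kg gives Vt = 538.6 mL). Comparing the device RR against
the simulation's true per-window breath count:

```r
agreement_report(res$windows$RR_brpm, rec$truth$windows$n_breaths * 2)
```

```
<agreement_report> n = 10
  r = 0.1857 | MD = +1.200 | LoA = +3.941 / -1.541 | MAE = 7.36% (1.200 abs)
```

Here the device runs about one breath per window high — noise-driven extra
peaks in the end-expiratory pause — with limits of agreement of a few
breaths per minute; r is small only because the true rate barely varies in
this recording. The methods vignette (`vignettes/breathband-methods.Rmd`)
discusses when each number is informative.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/breathband.R simulate --scenario walking --duration 300 --seed 1 --out data/
Rscript inst/cli/breathband.R process  --front data/front.csv --back data/back.csv \
        --preset 5 --subject subject.yaml --out windows.csv
Rscript inst/cli/breathband.R agree    --device windows.csv --reference ref.csv \
        --column RR_brpm --out report.json
```

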
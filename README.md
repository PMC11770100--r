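# LarvaScreen

Automated cardiac phenotyping and dosing toolkit for zebrafish larva
screening.

Microfluidic screening platforms load single zebrafish larvae into
channels, encapsulate each animal in a ~5.56 µL droplet of dosing medium,
orient it by computer vision and record bright-field video of the beating
heart. **LarvaScreen** reimplements the software core of such a platform
as a reusable, testable R package for the people who build or analyse
these systems:

* **Vision chain** — larva presence detection, eye segmentation
  (median filter → binarise → erode → dilate, two-stage Otsu threshold),
  head-forward vs tail-forward orientation calls, per-frame coordinate
  tracking.
* **Cardiac pipeline** — ROI grayscale trace → zero-phase Butterworth
  band-pass → min–max normalisation → peak-counted heart rate; M-mode
  line-sampling matrices; ventricle segmentation and direct least-squares
  ellipse fitting; end-diastolic/end-systolic extrema and the indicator
  formulas

  Area = π/4·D_L·D_S  Volume = π/6·D_L·D_S²
  FAC = 100·(EDA−ESA)/EDA  SV = EDV−ESV  CO = SV·HR

  (lengths µm, areas µm², volumes nL, HR beats/min, CO nL/min).
* **Dosing maths** — injection-volume solver
  V_inj = C_target·V_droplet/(C_stock−C_target), gradient plans, and
  Beer–Lambert calibration fitting with absorbance→concentration
  inversion.
* **Phantom generators** — seeded synthetic beating-heart videos, larva
  frames and calibration tables with exact ground truth, so the whole
  pipeline is validated end to end without animal data.
* **Batch orchestration** — manifest-driven runs, skip-and-log failure
  policy, per-condition mean ± s.e.m. summaries, byte-deterministic
  report serialisation.

## Worked example

```r
library(LarvaScreen)

# a beating-heart phantom: 150 beats/min, end-diastolic axes 150/100 um,
# end-systolic 100/70 um (true FAC = 53.33%), 35 fps, mild pixel noise
ph <- generateHeartVideo(duration = 6, heartRate = 150, noiseSd = 5, seed = 1)
report <- analyzeCardiac(ph$video)
report
#> CardiacReport
#>   HR : 150.0 beats/min
#>   FAC: 53.63 %
#>   SV : 0.5193 nL/beat
#>   CO : 77.90 nL/min
#>   13 complete cycle(s); qc: band_widened, hr_near_band_edge
```

The report recovers the phantom's ground truth: HR exactly (150), FAC
within 0.3 percentage points (53.63 vs 53.33) and SV within 2%
(0.5193 vs 0.5288 nL). The `band_widened` flag records that the rate
chain detected a cardiac fundamental (2.5 Hz) above the default 0.2–2 Hz
analysis band and widened the filter accordingly — see the vignette for
why this matters for fast larval hearts.

Dosing a droplet:

```r
gradientPlan(5.56, stock = 110, targets = c(10, 50, 100))
#>   target_uM inject_uL
#> 1        10  0.556000
#> 2        50  4.633333
#> 3       100 55.600000

cal <- fitCalibration(generateCalibrationTable(slope = 0.01,
    noiseSd = 0.005, seed = 501))
cal
#> Calibration: A = 0.00993801 * C + 0.00431326 (R^2 = 1.0000), range 5-110 uM
```

A thin command-line front end with `phantom`, `orient`, `cardio`, `dose`
and `run` subcommands ships in `inst/scripts/larvascreen.R`.

## Documentation

The methods vignette (`vignettes/cardiac-phenotyping.Rmd`) describes the
cardiac model and its assumptions, the numerical choices (band
adaptation, interval-based rate estimation, the algebraic ellipse fit,
the area-extrema ED/ES rule), what the phantoms do and do not emulate,
and known limitations.
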
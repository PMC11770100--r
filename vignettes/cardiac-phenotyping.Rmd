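---
title: "Cardiac phenotyping and dosing for automated zebrafish larva screens"
author: "LarvaScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiac phenotyping and dosing for automated zebrafish larva screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LarvaScreen)
```

## The problem

Automated screening platforms load single zebrafish larvae (typically 5
days post-fertilisation) into microfluidic channels, encapsulate each
animal in a small droplet of dosing medium, orient it for lateral imaging
and record bright-field video of the beating heart. Turning such
recordings into pharmacologically meaningful numbers requires three kinds
of software, all of which this package provides:

1. a **computer-vision chain** that decides whether an animal is in the
   field of view, finds its eyes (the darkest, most compact features) and
   calls its travel direction (head- or tail-forward) so the control loop
   can flip it if needed;
2. a **cardiac quantification pipeline** that estimates heart rate (HR)
   from grayscale fluctuation in a region of interest, tracks the
   ventricular wall with M-mode-style line sampling and ellipse fitting,
   and derives fractional area change (FAC), stroke volume (SV) and
   cardiac output (CO);
3. **droplet dosing maths**: how much drug stock to inject into a
   droplet to reach a target concentration, and Beer–Lambert calibration
   to verify what the animal was actually exposed to.

Because no public recordings of such a platform exist, the package ships
seeded *phantom generators* that render beating elliptical ventricles and
larva silhouettes with exact ground truth. Every stage is validated
against phantoms end to end.

## The cardiac model

The ventricle in a lateral bright-field view is modelled as an ellipse
with long-axis diameter $D_L$ and short-axis diameter $D_S$ (microns).
The package uses the standard single-plane relations, with the ventricle
treated as a prolate ellipsoid of revolution about its long axis:

$$\mathrm{Area} = \tfrac{\pi}{4} D_L D_S, \qquad
  \mathrm{Volume} = \tfrac{\pi}{6} D_L D_S^2,$$

$$\mathrm{FAC} = 100 \cdot \frac{\mathrm{EDA} - \mathrm{ESA}}{\mathrm{EDA}}, \qquad
  \mathrm{SV} = \mathrm{EDV} - \mathrm{ESV}, \qquad
  \mathrm{CO} = \mathrm{SV} \times \mathrm{HR},$$

where EDA/ESA are the ventricular areas at end-diastole and end-systole
and EDV/ESV the corresponding volumes. Units are fixed package-wide:
lengths in µm, areas in µm², volumes in nL (1 nL = 10⁶ µm³), HR in
beats/min, CO in nL/min. `CardiacReport` objects enforce
$\mathrm{CO} = \mathrm{SV} \times \mathrm{HR}$ and
$0 \le \mathrm{FAC} \le 100$ as class validity.

### Heart rate from the ROI trace

The mean grayscale of a rectangular ROI containing the ventricle
oscillates at the heart rate as the dark wall sweeps through it. The
chain is: `extractRoiTrace()` → `bandpass()` (zero-phase Butterworth,
forward–backward, so peak times are not shifted; default order 4) →
`normalizeTrace()` (min–max to [0, 1]) → `heartRate()` (prominence- and
separation-gated peak picking).

Two numerical choices deserve comment:

* **Rate from intervals, not raw counts.** `heartRate()` returns
  $60 (n_{\text{peaks}} - 1) / (t_{\text{last}} - t_{\text{first}})$
  rather than count ÷ duration. A raw count over a 10 s record is
  quantised in steps of 6 beats/min and biased by whether a peak happens
  to fall at the record edge; the interval form is exact on periodic
  signals and agrees with an all-local-maxima brute-force counter on
  clean traces (a property the test suite asserts).
* **Band adaptation.** The conventional analysis band is 0.2–2 Hz, and
  it is the package default. But healthy larval hearts routinely beat at
  2.5–3 Hz, where a fixed 2 Hz edge attenuates the fundamental by an
  order of magnitude — below the boundary-artefact floor of the 0.2 Hz
  high-pass edge — making peak counting meaningless. We verified this
  empirically: with the fixed default band, phantoms beating at 150
  beats/min come back at ~12 beats/min. `estimateHeartRate()` therefore
  runs a periodogram pre-check on the raw trace and widens the high edge
  to 1.5× the dominant cardiac frequency whenever that frequency exceeds
  90% of the edge, recording a `band_widened` QC flag. `bandpass()`
  itself stays faithful to whatever band it is given (the trace is
  demeaned and reflection-padded to suppress edge transients of the
  forward–backward pass). Users who need the literal fixed band can call
  `estimateHeartRate(..., adaptBand = FALSE)`.

### Wall motion, ellipse fitting and ED/ES

`buildMMode()` samples grayscale intensity along a fixed line through
the ventricle (bilinear interpolation, one sample per pixel of line
length) in every frame and stacks the profiles into a matrix $I[t, x]$ —
the light-microscopy analogue of M-mode echocardiography. The width of
the dark band in each row beats at the heart rate, which the tests
verify by autocorrelation.

`segmentVentricle()` binarises each frame (Otsu by default, dark-object
convention, configurable polarity), keeps the largest connected
component, fills holes and extracts the boundary chain.
`fitEllipse()` then fits a conic constrained to an ellipse by direct
algebraic least squares (the numerically stable partitioned formulation
of the Fitzgibbon constraint $4AC - B^2 = 1$). The algebraic objective
was chosen over iterative geometric fitting because it is closed-form,
deterministic, exact on noise-free conic data (to $10^{-6}$ µm in the
tests) and ellipse-specific — it cannot return a hyperbola on noisy
edges. Points are centred before fitting for conditioning; axis lengths
are converted to µm via the pixel size and ordered so $D_L \ge D_S$.

End-diastole and end-systole are defined on the *area* series
$\tfrac{\pi}{4} D_L(t) D_S(t)$: cycles are delimited by successive
diastolic maxima of a lightly smoothed copy (moving average of about a
tenth of a second), and within each cycle the axes are read at the raw
area maximum (ED) and minimum (ES). Using area extrema rather than
per-axis extrema reads both axes at a common frame, the way a
sonographer reads an M-mode still, and guarantees EDA ≥ ESA by
construction. Per-cycle FAC and SV are aggregated by arithmetic mean
over complete cycles; the incomplete terminal cycle is implicitly
discarded because a cycle requires two delimiting maxima.

Frames where segmentation fails are flagged and linearly interpolated in
the axis series rather than aborting the recording; a recording fails
only when no frame is usable or no complete cycle exists (e.g. a static
heart, which the rate chain already rejects as having no signal).

## The vision chain

* `detectLarva()`: light Gaussian blur, Otsu (or manual) threshold with
  dark-object convention, connected components; present iff the largest
  component reaches `minArea`. A minimum-contrast guard (default 20
  grayscale units between object and background class means) keeps
  pure-noise frames from percolating into spurious detections.
* `segmentEyes()`: median filter (3×3 default) → binarise → erode →
  dilate (3×3 disc, 1 iteration each), then size and circularity gates,
  keeping at most the two largest components. The default threshold is
  *two-stage Otsu*: the first stage separates animal from background,
  the second, computed on animal pixels only, isolates the darkest class
  — the eyes. This makes the default robust to the three-mode histogram
  (background/body/eyes) where plain Otsu would return the body.
* `determineOrientation()`: projects the mean eye position and the body
  centroid onto the channel axis; head-forward iff the eyes lead by more
  than a dead-band ε (default 2 px), tail-forward iff they trail by more
  than ε, otherwise undetermined. Zero detected eyes is an undetermined
  call, not an error. When two candidate eyes lie further apart than a
  configurable maximum inter-eye distance, `orientLarva()` calls the
  frame undetermined rather than guessing. The eye-to-direction rule is
  this package's own design — platform descriptions name the
  morphological operations but not the decision rule — and the projected
  lead with a dead-band is the simplest rule that is exactly
  antisymmetric under mirroring, a property the tests assert.

Coordinates are 1-based throughout (x = column, y = row, y increasing
down the rows), and angles are measured in degrees from +x toward +y.

## Dosing and calibration

A droplet of volume $V_d$ (µL) of drug-free medium receiving $V_{inj}$
of stock at concentration $C_s$ reaches
$C = C_s V_{inj} / (V_d + V_{inj})$; `injectionVolume()` inverts this to
$V_{inj} = C_t V_d / (C_s - C_t)$, assuming complete, instantaneous
mixing (no kinetics are modelled). The reference droplet volume in the
examples, 5.56 µL, is the encapsulation plug of the chip geometry the
package targets. `fitCalibration()` fits the Beer–Lambert line by
ordinary least squares with a free intercept by default — whether a real
calibration forces the origin is instrument-specific, so
`throughOrigin = TRUE` provides the constrained alternative (with the
uncorrected-total-sum-of-squares $R^2$ convention usual for
through-origin fits).

## What the phantoms emulate — and what they do not

`generateHeartVideo()` renders a filled ellipse whose axes follow a
raised-cosine oscillation between systolic and diastolic extremes —
smooth, with a single extremum per half cycle, which is what wall-motion
traces look like but deliberately *not* a physiological waveform (real
cycles have asymmetric filling phases). Defaults are chosen as a
realistic larval ventricle: 150/100 µm long/short axis at end-diastole,
100/70 µm at end-systole (FAC = 53.3%), 150 beats/min, 35 fps, 1 µm/px,
dark lumen (60) on light field (180). Noise is additive Gaussian,
clipped to [0, 255] — the simplest controllable corruption for recovery
tests. The generators refuse physically meaningless requests: frame
rates at or below twice the beat frequency, recordings shorter than one
period, inverted axis extremes.

`generateLarvaFrame()` renders an elongated body ellipse with two dark
eye discs offset along the axis; the sign of the offset defines
head-forward. `generateCalibrationTable()` produces linear
concentration–absorbance pairs, by default at the five-standard series
5/20/50/80/110 µM.

Passing tests on phantoms therefore demonstrates that the *algorithms*
recover known ground truth under controlled corruption. It does not
demonstrate robustness to out-of-focus frames, pigmentation, pericardial
shadows, blood-cell texture, atrial interference or illumination drift —
real-data properties the phantoms do not model. The QC flags and
per-frame failure accounting exist precisely because real recordings
will exercise them more than phantoms do.

## Problem sizes and determinism

The test-suite and acceptance-script phantoms are sized for quick,
deterministic runs: 96×96 px stacks for rate recovery (a 12-cell grid of
HR ∈ {100, 120, 150, 180} beats/min × noise σ ∈ {0, 5, 10}, 10 s at 35
fps), a 192×192 px stack for full geometric analysis (6 s), and 200
larva frames for orientation accuracy. All generators take an integer
seed and restore the caller's RNG state; identical seeds give
bit-identical frames, and `runExperiment()` plus `writeReports()`
produce byte-identical output trees for identical inputs (no timestamps
are written), so batch runs can be diffed.

## Known limitations

* Single-ellipse model: the atrium is not modelled and atrial
  contribution to the ROI trace is treated as noise.
* The volume formula assumes rotational symmetry about the long axis;
  true larval ventricles deviate, so SV/CO are comparable within a
  study, not absolute.
* Segmentation assumes the ventricle is the largest dark object in the
  search window; a pigmented swim bladder inside the window would need a
  manual `roiHint`.
* The band-adaptation heuristic assumes the dominant spectral peak above
  0.2 Hz is cardiac; gross motion artefacts at higher power would
  mislead it (the `band_widened` flag makes this auditable).

## A worked example

```{r example, eval = FALSE}
ph <- generateHeartVideo(duration = 6, heartRate = 150, noiseSd = 5,
    seed = 1)
report <- analyzeCardiac(ph$video)
report
#> CardiacReport
#>   HR : 150.0 beats/min
#>   FAC: 53.63 %
#>   SV : 0.5193 nL/beat
#>   CO : 77.90 nL/min
#>   13 complete cycle(s); qc: band_widened, hr_near_band_edge
ph$truth$fac   # 53.33 — ground truth recovered within 0.3 points
```
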
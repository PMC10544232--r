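---
title: "Methods: quantifying larval zebrafish cardiac function from video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying larval zebrafish cardiac function from video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfpulse)
```

zfpulse quantifies cardiovascular performance of larval zebrafish from
high-speed microscopy: ventricular contractility from bright-field heart
recordings, dorsal-aorta blood-flow velocity (BFV) from kymographs and from
single-cell tracking, and membrane-fluorescence foci contrast from confocal
line profiles. This vignette documents the models behind each estimator, the
parameters that matter, the synthetic-data generator used to validate them,
and the numerical choices where the design was genuinely open.

## Ventricular contractility

The ventricle in a ventral bright-field view is modelled as an ellipse; its
rotation about the long axis gives a prolate spheroid. With **full** axis
lengths $L$ (major) and $D$ (minor), in micrometres:

$$V = \tfrac{1}{6}\pi L D^2, \qquad A = \tfrac{\pi}{4} L D .$$

An important convention: $L$ and $D$ are full axes, not semi-axes. Under that
reading $\tfrac{\pi}{4}LD$ is exactly the ellipse area
($\pi \cdot \tfrac{L}{2} \cdot \tfrac{D}{2}$) and $\tfrac{1}{6}\pi L D^2$
equals the standard prolate-spheroid volume
$\tfrac{4}{3}\pi\,(L/2)(D/2)^2$; with semi-axes neither identity holds.
`fit_ellipse()` therefore reports full axis lengths.

Per-frame outlines (digitised manually, or extracted from masks with
`contours_from_masks()`) are fitted by a direct least-squares conic fit with
an ellipse constraint, numerically conditioned by centring and scaling; on
vertices sampled exactly from an ellipse the axes are recovered to
floating-point precision. The fit is point-set based, so vertex ordering is
irrelevant. Fewer than five vertices, or collinear ones, raise a
"degenerate contour" error.

The fitted area trace drives beat detection (`detect_beats()`): the trace is
smoothed with a centred moving average of `round(frame_rate/10)` frames —
wide enough to remove pixel-quantisation ripple, narrow enough (0.1 s at
150 frames/s) not to shift the extrema of beats of 0.2 s or longer — and
end-diastolic (ED) frames are local maxima, end-systolic (ES) frames local
minima, with topographic prominence of at least 20% of the trace range.
Each ED pairs with the next ES; beat intervals are successive ED-to-ED
times. From ellipse volume/area at those frames, per beat:
EDV, ESV, $SV = EDV - ESV$, $EF = SV/EDV$, and
$FAC = (A_d - A_s)/A_d$. For a uniform axis scaling $s$ between ED and ES,
$EF = 1 - s^3$ and $FAC = 1 - s^2$ exactly — a property the tests exploit.

Metrics are averaged across all complete beats by default; the original
manual workflow measures single chosen frames, so `single_beat = TRUE`
reproduces that mode. Heart rate is `60 / median(beat_intervals)` (the
median resists a single missed beat) and `rhythm_cv` — the coefficient of
variation of beat intervals — is the rhythm-regularity readout; the
`irregular` flag fires above a configurable 0.1, a threshold of ours since
published assessments of rhythm are qualitative.

The mask route thresholds each lightly smoothed frame at 50% of its dynamic
range and keeps the boundary pixels of the resulting region, ordered by
angle about the centroid. Thresholding quantises the boundary at about half
a pixel, which propagates to roughly 0.01 absolute error in EF at the
default geometry; tests budget for exactly that.

## Kymograph velocimetry

`build_kymograph()` samples each frame by bilinear interpolation at
unit-arclength steps along a vessel-centreline polyline, averaging
`line_width` pixels perpendicular to the local tangent. Rows are frames
(time), columns distance, so a cell moving at constant speed draws a streak
of slope $m = \Delta\text{frames}/\Delta\text{distance}$ and

$$v = \frac{\text{pixel\_size} \times \text{frame\_rate}}{m}:$$

the steeper the streak towards the time axis, the slower the flow.
Stationary cells (vertical streaks, $m \to \infty$) give $v = 0$.

Streak orientation is estimated per sliding 16-frame window (50% overlap; at
400 frames/s this resolves phases of cycles of 150 ms and longer) by
structure-tensor eigenanalysis: Gaussian-derivative gradients at scale
1.5 px, gradient products smoothed at integration scale 4 px, then averaged
over the window and eigen-decomposed in closed form. The eigenvector of the
smaller eigenvalue is the streak direction. Windows whose orientation
coherence $(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)$ falls below 0.2 have
no dominant orientation (crossing streaks, empty vessel) and are flagged
missing rather than forced to zero; they are interpolated for phase
segmentation but excluded from summaries. The structure tensor was chosen
over Radon-style profiling for robustness to streak crossings; a Radon
check remains available as a test oracle. On ideal streak patterns the
estimator is accurate to well under 1%.

Phase segmentation thresholds the lightly smoothed velocity trace at the
midpoint of its 10th and 90th percentiles: above is systole, below
diastole. A flat trace (10–90 range under 5% of the mean) is labelled all
diastole with a warning, since phases are undefined without pulsatility.

`phase_summary()` reports *peak-systolic* and *end-diastolic* velocity: each
contiguous systolic run contributes its 0.95-quantile velocity, each
diastolic run its 0.05-quantile, averaged across runs. The mean over all
samples of a phase would, for a sinusoidal waveform, sit at
$2/\pi \approx 0.64$ of the way from midline to extreme rather than at the
extreme, which is not what a reader of a kymograph angle measures — the
visually dominant steep/shallow angle tracks the waveform extremes, as does
the clinical peak-systolic/end-diastolic convention. Runs cut off by the
trace boundary are incomplete cycles and are dropped when complete runs
exist. `extreme_quantile = 0.5` recovers plain per-phase medians. Angles are
reported as $\arctan(m)$ in degrees from the distance axis, so slower flow
shows as a steeper angle. Since published kymograph readouts are relative
(angles), `streak_velocity(calibrated = FALSE)` returns px/frame slopes
alongside the calibrated µm/s output.

## Single-cell tracking

`detect_cells()` runs scale-normalised Laplacian-of-Gaussian detection over
a small sigma ladder (1.5–4 px, four scales, spanning blood-cell radii of
2–6 px) with sub-pixel refinement by the intensity-weighted centroid of a
5×5 patch; a full Gaussian fit adds nothing at these signal-to-noise
ratios. `link_tracks()` uses greedy nearest-neighbour assignment per frame
transition (matches beyond `max_disp` px/frame rejected; gaps closed up to
`max_gap` frames). Greedy linking is adequate — and provably equal to
optimal assignment — in the sparse, quasi-one-dimensional dorsal-aorta
scene, where cells travel in parallel and stay separated; it is a documented
limitation for crowded scenes, which this package does not target.

`kinematics()` differentiates positions by central differences (velocity)
and differentiates speed again for acceleration. The per-recording maximum
velocity `v_max` is the largest per-beat peak of the per-frame mean speed
across cells, where each beat's peak is read as the 95th percentile of the
*lightly smoothed* trace within the beat window: raw per-step maxima are
dominated by localisation jitter and transient detection doublets when two
cells cross. How a "maximum velocity" should aggregate (per cell, per beat,
per larva) is not standardised; per-larva maximum of per-beat peaks is this
package's documented choice.

## Membrane-profile foci quantification

`sample_profile()` mirrors an intensity-profile tool: bilinear samples at
unit-pixel arclength steps along a membrane path, averaged over `width_px`
perpendicular pixels, normalised by the profile maximum (so the output is
gain-invariant by construction). `foci_quant()` smooths with a 5-sample
moving average, finds peaks with prominence ≥ 0.1 (relative units) and
relative height ≥ 0.5 (foci are bright; faint noise bumps are not foci),
and forms `ratio = mean(peaks) / mean(troughs)` — the
average-maximum/average-minimum reading of the dotted-line quantification;
a global max/min alternative is available via `global_extrema = TRUE`.
Profiles with no peak/trough structure return ratio 1 with a `diffuse`
flag, which is precisely the readout expected of a delocalised mutant.

Two value-readout choices matter numerically. Peak values come from the
unsmoothed profile (median of the 3 samples at the located maximum): the
moving average attenuates a sharp Gaussian focus by ~3%, a bias the short
median avoids without admitting single-sample spikes. Trough values are
medians of the baseline-level samples of each inter-peak segment after
excluding flanks within three estimated SDs of each focus (SD from the
half-height half-width): a segment *minimum* is an extreme-value statistic
whose downward bias under noise inflates the ratio by up to 20% at 5%
noise, whereas the flank-excluded median is unbiased on the flat baseline
stretches. Whether a figure-level ratio is formed per profile or pooled is
unstated in published material; this package computes per-profile ratios
and averages them downstream.

## The synthetic-data generator

Every estimator is validated by parameter recovery on synthetic inputs with
ground-truth sidecars, generated at the acquisition settings of the assays
they emulate:

* **Beating heart** (`make_beating_heart()`): a filled soft-edged ellipse
  whose full axes oscillate between end-diastolic (default 100 × 60 µm) and
  end-systolic (default 80 × 48 µm, i.e. EF 0.488, FAC 0.36) values with a
  raised-cosine waveform, 150 frames/s for 10 s, beat period 0.4 s
  (150 bpm, a typical larval rate). The true volume waveform of a larval
  ventricle is not documented; the raised cosine is a stand-in with
  identifiable extrema, which is all beat detection requires. Optional
  per-beat Gaussian period jitter produces arrhythmic rhythms with known
  interval CV. Ground truth carries the analytic EDV/ESV/SV/EF/FAC and
  heart rate.
* **Pulsatile flow** (`make_flow_video()`): bright disks advected along a
  straight vessel with
  $v(t) = v_{dia} + (v_{sys}-v_{dia})(1+\sin 2\pi t/T)/2$
  (defaults 800/200 µm/s, $T$ = 0.4 s — typical larval dorsal-aorta
  values), 400 frames/s, 500 frames. Cells leaving the field re-enter at
  the inlet so density is stationary for tracking tests.
* **Ideal kymographs** (`make_kymograph_pattern()`): parallel streaks of
  prescribed px/frame slopes with isotropic 1-px Gaussian cross-section,
  piecewise-linear in time.
* **Membrane profiles** (`make_membrane_profile()`): a flat baseline plus
  Gaussian foci peaking at `focus_height`, centres at least `6 * focus_sd`
  apart, with `foci_ratio = focus_height/baseline` as truth.

Images are 16-bit grayscale (intensities scaled to [0, 60000], additive
Gaussian noise clipped to the valid range), written as multi-page TIFF with
CSV ROIs and JSON truth sidecars; coordinates are 0-based row/column pixel
indices with physical calibration applied only at metric computation. All
generators are bit-reproducible under a fixed seed.

What the generator deliberately does **not** emulate: myocardium texture
and wall thickness, optical point-spread blur, photobleaching, out-of-plane
motion, red-cell deformation, or vessel curvature. Passing recovery tests
therefore demonstrates correctness of the geometry and kinematics pipeline
under controlled conditions, not segmentation robustness on raw
bright-field footage — outlining a real ventricle remains a manual or
external-segmentation task by design.

## Statistics and conservation utilities

`compare_groups()` performs the comparisons these quantifications feed:
two-sided unpaired t test for two groups (pooled variance by default, since
"unpaired t test" conventionally means the pooled form; Welch via
`var_equal = FALSE`), one-way ANOVA for more, followed by Tukey HSD or
Holm–Šídák post hoc tests — the step-down Šídák adjustment
$p_{(i)}^{adj} = 1-(1-p_{(i)})^{m-i+1}$ (cumulative-maximum enforced) is
implemented in-package as no installed routine provides it. Group summaries
report both SD and SEM, since figure conventions vary. `delta_delta_ct()`
implements relative qPCR quantification, $2^{-\Delta\Delta Ct}$.

`global_align()` wraps Needleman–Wunsch global alignment with affine gaps
(BLOSUM62, gap open 10, extend 0.5 — common web-tool defaults, documented
as an assumption since published identity figures rarely name their tool).
The gap convention is that a gap of length $L$ costs
$open + L \times extend$. Identity is identical columns over alignment
length. `residue_conserved()` maps a 1-based reference residue position
through the alignment (matching clinical p.(R1230C)-style numbering) and
reports per-ortholog conservation, with gapped columns flagged unalignable
rather than unconserved.

## Problem sizes and tolerances used in validation

The test-suite and acceptance-script simulations use 2–2.5 s heart
recordings (300–375 frames) and 300–500-frame flow recordings, 20 synthetic
hearts spanning EF 0.1–0.6, 10 flow seeds for end-to-end phase recovery,
and 10 noisy membrane profiles — sizes chosen so the full validation runs
in minutes while every recovery band (EF within 0.01 noiseless / 0.05 at 5%
noise; streak slopes within 2%; phase velocities within 10%; v_max within
5%; foci ratio within 5%) is exercised with margin. Intensity noise levels
in tests are 5% of the dynamic range (hearts) or of the focus height
(profiles), the upper end of what the recovery bands are specified for.

## Known limitations

* No automatic ventricle segmentation from raw bright-field video, and no
  atrial metrics.
* Greedy linking will swap identities in crowded or strongly overlapping
  scenes.
* Kymograph velocities assume motion along the ROI; off-axis flow
  components are invisible.
* The uncalibrated (px/frame) kymograph mode exists because published
  angle-based readouts are relative; comparing absolute velocities across
  setups requires the spatial and temporal calibration to be correct.
* The diffuse-signal fallback (ratio 1) is a floor, not an estimate: truly
  diffuse membranes have no peak/trough structure to quantify.
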
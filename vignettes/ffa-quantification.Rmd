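---
title: "Quantifying choroidal neovascularization from fluorescein fundus angiograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying choroidal neovascularization from fluorescein fundus angiograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffaquant)
```

## The measurement problem

Laser rupture of Bruch's membrane in rodents is the standard model of
choroidal neovascularization (CNV). Fundus fluorescein angiography (FFA)
images the lesions in vivo: leaky new vessels retain fluorescein and
appear hyperfluorescent, while avascular chorio-retinal burns appear
hypofluorescent. Two acquisition artifacts stand between the raw frames
and a usable number:

* **Magnification.** The camera lens presses on the cornea; the resulting
  shortening of the optical path magnifies the fundus image by a factor
  that varies between animals and sessions. Raw pixel areas are therefore
  not comparable across eyes.
* **Background.** Choroidal background fluorescence is mottled and varies
  across the fundus, so a lesion's absolute mean grey value is dominated
  by where it happens to sit.

`ffaquant` implements the corrections for both, a composite severity
score, the bolus kinetics needed to choose the analysis frame, and group
statistics.

## The quantification model

For each lesion with a grader-drawn maximal border (imported from ImageJ
`.roi` files, a polygon JSON sidecar, or binary masks):

1. **Area.** The outline is rasterized (conventions below) and the pixel
   count `A_lesion` recorded. The session's optic nerve head (ONH)
   outlines give `mean(A_ONH)`, and the reported size is the
   dimensionless `A_norm = A_lesion / mean(A_ONH)`. Because both areas
   scale with the square of the magnification, `A_norm` is
   magnification-free; the package verifies <2% drift across
   magnifications 0.85–1.15 (the residual is rasterization noise).
2. **Background.** An annulus is built around the lesion: inner border =
   lesion border, outer border = inner border scaled ×2 about the lesion
   centroid. For a circle this is the twice-the-radius rule and gives an
   annulus/lesion pixel ratio of exactly 3; centroid scaling extends the
   rule to arbitrary outlines while preserving that ratio (an
   equal-area-circle construction was rejected because it can overlap
   elongated lesions). Six square vessel-free patches inside the annulus
   provide `F_bg` as the mean of patch means.
3. **Intensity.** `F_net = mean grey(lesion pixels \ vessel pixels) −
   F_bg`, in grey levels, computed in floating point with no clamping to
   the acquisition bit depth. Negative values are expected for burns.
4. **Severity.** `I_corr = F_net × A_norm`, i.e. the lesion's summed
   above-background grey value expressed in ONH-area units. It is bilinear
   in its two factors by construction.

All intensity work is done on one analysis frame per session, by default
the frame nearest 10.2 s post intravenous injection — the empirical
cohort peak of CNV fluorescence; a per-lesion-peak mode is available
through `detect_peak()` when cross-animal comparability is not required.

## Kinetics

Per-lesion traces (`extract_trace()`) support:

* `detect_appearance()` — first time the trace exceeds baseline + k·SD
  (default k = 3) with the next sample also above threshold. The 2-frame
  persistence guards against single-frame noise; the baseline window
  defaults to the first max(3, 5%) samples.
* `detect_peak()` — argmax of a moving-average-smoothed copy (window 5
  frames at video rate, 1 at slow rates). Smoothing only locates the
  peak; reported intensities are never smoothed. A maximum on the final
  frame is flagged *censored*: on the intraperitoneal schedule the
  logarithmic rise has no interior maximum, so IP peak times are
  right-censored at the 10-minute window end. Note that with noticeable
  noise the literal location of a censored maximum within the terminal
  plateau is arbitrary; the censoring flag, not the time, is the
  meaningful output there.
* `fit_kinetics()` — bounded Levenberg–Marquardt least squares of either
  an intravenous gamma-variate `v(t) = A((t−t₀)/θ)^α e^{α(1−(t−t₀)/θ)}`
  (parameterized so A is the peak value, reached at t₀+θ) or an
  intraperitoneal saturating rise `A·log(1+(t−t₀)/τ)`, each plus a
  constant baseline. These functional forms are this package's modelling
  choice layered on the qualitative behaviour of the two routes (a sharp
  ~15 s flux for IV, a slow log-like rise for IP); they are empirical
  conveniences, not perfusion models, and sit behind a small interface so
  other forms can be substituted. Failed fits return an object flagged
  `converged = FALSE`; peak detection remains available.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `annulus_scale` | 2 | — | the twice-the-radius background rule |
| `patch_side` | max(5, r_eq/6) | px | six patches must fit a thin annulus; r_eq = equivalent lesion radius |
| appearance `k` | 3 | baseline SD | conventional 3-sigma onset |
| `smooth_window` | 5 (video) / 1 | frames | one sixth of the ~1 s peak plateau at 30 fps |
| `target_time` | 10.2 | s | cohort peak of CNV fluorescence (IV) |
| t-test `variance` | pooled | — | Student's t as named; Welch selectable |
| `exclude_weeks` | 1 | week | week-1 borders are too diffuse to outline |

The minimum vessel-free annulus area for quantification is 6 × patch
area; below it the lesion is flagged unquantifiable rather than measured
badly.

## The six-patch selection rule

Human graders pick "representative" background patches by eye. To be
reproducible the package uses a deterministic procedure: every annulus
pixel whose full square patch fits inside the vessel-free annulus is a
candidate; six target angles 60° apart (seeded random start) are visited
in turn and the candidate nearest each target angle about the lesion
centroid is taken, skipping candidates whose patch would overlap an
earlier pick (Chebyshev distance < side); exact angular ties are broken
by a seeded random key. This spreads the samples around the lesion the
way a grader would, is identical for identical (frame, annulus, seed),
and never touches vessel or lesion pixels — the latter is asserted on
every call.

## Rasterization conventions

Coordinates are 0-based, x = column, y = row, with pixel centres at
integer positions. A polygon owns a pixel when its centre is inside under
the even-odd (crossing-number) rule; self-intersecting outlines therefore
exclude their doubly-wound regions, matching ImageJ's behaviour for
freehand selections. An axis-aligned square with corners at (0,0) and
(10,10) covers exactly 100 pixels under this rule. The rasterizer is
verified exactly against an independent point-in-polygon oracle on
hundreds of random polygons. Degenerate inputs (polygons with <3
vertices, outlines entirely outside the frame, empty masks) are rejected
with the lesion id in the message.

ONH normalization averages over all ONH outlines supplied for a session
(several graders and/or frames may contribute). Annulus pixels clipped at
the frame border are dropped and reported as `clip_fraction`; background
sampling then proceeds on the remaining ring under the minimum-area
guard.

## What the phantom emulates — and what it does not

`generate_scene()` renders: a mottled choroidal background (smooth seeded
Gaussian field), a seeded branching vessel tree (widths ~3–8 px, a
plausibility device with no biophysical claim), the ONH disc,
elliptical CNV/burn lesions with painted contrast (+60 / −15 grey by
default over background 40), an optional Gaussian leak halo beyond the
true border (so that area overestimation from diffuse leakage is a
testable failure mode rather than an accident), per-compartment bolus
kinetics ordered as observed in vivo (vessels first at ~6.6 s, lesion
last at ~7.5 s, peaks near 10.1–10.2 s for IV; delayed log-rise for IP),
a per-session magnification factor, and additive Gaussian noise. Frames
are 1024×768, 8 bits per channel, with the signal confined to the green
channel and low-amplitude structured decoys in red and blue so channel
extraction is itself under test. Scenes are bit-exact functions of
(spec, seed).

`generate_cohort()` emulates the treatment study: two groups (default 16
eyes each, 3–4 lesions per eye — lesion-level n, as in the reported
group sizes), PBS lesions at normalized area 2.0 ± 0.35 and net
fluorescence 60 ± 8 grey, with programmed additive treatment effects
(default −0.6 ONH units and −20 grey, a strong anti-angiogenic
response), per-eye magnification U(0.9, 1.15) and per-eye seeds derived
from the master seed.

Passing tests on phantoms demonstrate that the *computational* chain —
geometry, background estimation, normalization, kinetics, statistics —
is correct and unbiased under known truth. They do not validate the
biological realism of the scenes: real angiograms have focus gradients,
breathing motion, iris-shadow vignetting, heterogeneous leak dynamics
and grader-to-grader border variability that the phantom does not model.
Real-data conclusions still depend on grader-drawn borders.

## Numerical choices and problem sizes

* Grey arithmetic in doubles throughout; rendered phantoms quantize to
  the bit depth only at frame construction.
* Nearest-frame selection breaks ties toward the earlier frame; targets
  beyond the sequence clamp to the last frame with a warning.
* `ttest_two_tailed()` adopts t = 0, p = 1 when both samples are
  constant and equal (the degenerate case `stats::t.test()` refuses).
* No multiple-testing correction by default (mirroring the original
  analysis); Holm is available.
* Fit starting values come from the detected appearance and peak;
  parameters are bounded (A, θ, τ > 0, α ∈ [0.1, 10]) and
  non-convergence is a flag, not an error.
* Test and acceptance problem sizes were chosen for a desk-scale run:
  unit-test scenes are 240–420 px wide, the patch-safety property uses
  100–200 seeded phantoms, kinetics recovery 100 traces at the full
  30 fps × 120 s schedule, t-test calibration 1000 null and 400
  powered replicates, and the end-to-end check runs the full-size
  (1024×768, 16 + 16 eyes) cohort once.

## Known limitations

* Lesion-level testing pseudo-replicates eyes with several lesions; the
  `by_eye = TRUE` mode averages within eye first and is the conservative
  alternative.
* The six-patch rule samples wherever the annulus allows; immediately
  adjacent to a strongly leaking lesion the annulus itself is
  contaminated by the halo, biasing net fluorescence slightly downward —
  visible in phantoms with wide halos and inherent to any local
  background definition.
* The ImageJ `.roi` support covers the polygon/freehand integer subset
  only (the formats the freehand selection tool produces).
* Automatic lesion segmentation is deliberately out of scope: borders
  are grader-drawn inputs.
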
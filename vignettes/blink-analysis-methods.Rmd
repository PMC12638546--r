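---
title: "Methods: quantified eye-blink analysis from high-frame-rate video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantified eye-blink analysis from high-frame-rate video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blinkscope)
```

## The problem

An eye blink lasts roughly 100–400 ms. At the standard 30 fps a blink
spans only a handful of frames, which is too coarse to resolve the
closing, fully closed and opening phases, or to tell an incomplete
blink (the lid never covers the eye) from a complete one. blinkscope
analyzes high-frame-rate video (nominally 240 fps, any rate from about
60 fps upward) of an eye region and produces, per blink: a single
normalized image summarizing the whole lid motion, a displacement
trace, a three-phase segmentation, a pattern label (normal /
incomplete / consecutive) and a parameter set (durations, speeds,
displacement, closed-phase ratio), plus per-video summary statistics
(blink rate, mean/SD duration, closure proportion, incomplete ratio).

The pipeline is deterministic: the same input and configuration always
give byte-identical CSV/JSON outputs.

## Pipeline overview

1. **Signals.** Two per-frame series: the mean grayscale intensity,
   and a simulated dynamic-vision (event-camera) signal — each pixel
   keeps a reference brightness and fires an event, resetting the
   reference, whenever the current brightness differs from it by more
   than a threshold (default 15 of 255). A blink shows up as a peak in
   the intensity profile and as two event bursts (closing, opening).
2. **Detection.** The intensity profile is smoothed with a moving
   average of `round(fps / 48)` frames; local extrema above a
   prominence floor (4 × MAD of the first difference, never below 2
   intensity units) become blink apices `x2`; walking outward until
   the profile returns within 10 % of the peak excursion of baseline
   gives the span `x1..x3`. Whether a blink raises or lowers the mean
   intensity depends on the skin/eye contrast, so peak polarity is
   auto-detected per video. Overlapping spans are merged: a second
   blink that starts before the first has reopened never lets the
   profile return to baseline, so a consecutive-blink complex is one
   candidate. The event signal confirms each candidate: at least two
   bursts, or one burst covering at least half the span — the latter
   because a blink with no closed hold (typically an incomplete blink)
   reverses at full speed and its two bursts fuse into one.
3. **Filters.** Spans shorter than 50 ms (eyelid flutter) or longer
   than 1500 ms (micro-sleep) are rejected, as are candidates whose
   rise `y2 − y1` and fall `y2 − y3` differ by more than 20 % of the
   larger (an environmental intensity change, not a blink).
4. **Eyelid estimation.** Each accepted blink is cut out with 12
   context frames per side. The clip's first frame gives a
   binarization threshold (deepest histogram valley between the two
   highest peaks of a 5-bin-smoothed 256-bin histogram; Otsu when
   unimodal). Binary frame-to-frame changes accumulate into a dynamic
   image whose heaviest 8-connected blob (at 25 % of the maximum) is
   the eye; its bounding box plus a 5 px margin is the ROI. Per frame,
   the upper eyelid is the first dark pixel of each ROI column,
   cleaned by iterative polynomial outlier removal and completed by
   evaluating the fitted polynomial in interior gaps.
5. **Blink matrix.** Per-frame curves are conformed to the modal
   defined-span length (ties to the larger; longer curves
   center-trimmed, shorter ones extended by polynomial
   extrapolation), resampled to 500 columns, converted to
   upward-positive heights, and affinely mapped so the first frame
   spans exactly 0.2–0.7. The jet-palette projection with red dotted
   lines every 0.1 s is the single-image blink visualization.
6. **Phases and patterns.** The displacement trace is the mean of the
   10 center columns per row. The Complete Closed phase is the
   contiguous run below 0.25 around the global minimum; Closing runs
   from blink start to it; Opening is the remainder. A minimum above
   0.3 means no closed phase and the label *incomplete*. A reopening
   peak between two minima that stays below 90 % of the open-to-closed
   span marks a *consecutive* blink.

## Tunable parameters

All tunables live in `blink_config()`; the method constants
(`method_constant_keys()`) — 50/1500 ms, the 20 % symmetry bound, the
0.25/0.3 displacement thresholds, 500 columns, the 0.2–0.7 range, and
the 0.1 s gridlines — define the analysis itself and should not
normally be changed. The remaining defaults and their reasons:

* `event_threshold = 15` (intensity units): large enough that
  Gaussian sensor noise of a few units almost never fires, small
  enough that the ~140-unit skin/eye contrast fires reliably.
* `smooth_window = round(fps/48)` (~5 frames / 21 ms at 240 fps):
  suppresses frame noise without blurring a 50 ms flutter into the
  valid duration range.
* `min_prominence = 2`: absolute floor so a blink-free video cannot
  seed candidates from noise alone.
* `pad = 12` frames (50 ms at 240 fps): open-eye context on both clip
  ends, needed by the first-frame binarization threshold and the
  first-row matrix normalization.
* `poly_degree = 2`, `outlier_tol_px = 3`, `max_iter = 20`: the
  eyelid arch is close to parabolic at eye-region resolutions around
  0.5 MP; 3 px tolerates raster rounding and mild noise.
* `reopen_frac = 0.9`, `reopen_prominence = 0.05`: "fully reopened"
  means regaining 90 % of the open-to-closed span; a reopening peak
  must rise at least 0.05 normalized units above its neighboring
  minima so trace noise cannot fake a consecutive blink.
* `start_eps = 0.01`: a blink starts/ends where the trace leaves /
  regains the open level by 0.01 normalized units.

Pixel-unit defaults assume an eye-region video around 0.5 MP; all are
config keys because no resolution-dependent scaling rule is built in.

## Numerical choices

* **Outlier gate.** Each iteration fits by least squares and removes
  points whose residual deviates from the *median residual* by more
  than `max(tol, 3 × 1.4826 × MAD)`. Measuring deviation from the
  median residual rather than from zero matters: a group of outliers
  drags the fit toward itself until its absolute residuals look
  ordinary (masking), while deviations from the robust center still
  expose it. Because least squares has breakdown zero, gross
  contamination (several points displaced by tens of pixels) can
  still hide; when the initial fit shows deviations beyond 5 × tol, a
  deterministic least-median-of-squares seed — exact minimal-sample
  fits over a bounded candidate set, scored by median absolute
  residual — first removes points deviating by more than 10 × tol
  from the seed. The 10 × tol floor is deliberate: near closure the
  eyelid arch clamps flat at the lid corners and is legitimately
  non-parabolic by 5–15 px, and a majority fit without the floor
  would discard the real lid. The inlier set only shrinks, so the
  procedure terminates and is idempotent; classical random-sampling
  RANSAC is kept only as a test oracle (exhaustive minimal sampling),
  where the iterative scheme matches it on ≥ 98 % of randomized small
  instances.
* **Binarization** is computed once from the clip's first frame and
  reused (a per-frame mode exists for flicker-heavy input); the ROI is
  computed once per clip from the whole-clip dynamic image.
* **Ties and degenerate input.** Modal-length ties go to the larger
  length; center-trimming removes the extra column from the right;
  extension splits the deficit left-heavy — all fixed so outputs are
  bit-reproducible. A flat first-frame curve falls back to center
  normalization (center → 0.7, one ROI-height aperture across the
  0.2–0.7 span). A constant image has no histogram valley and is an
  error; a monotone displacement trace is "not a blink". Zero-length
  phases report `NA` speeds, never infinities.
* **Normalization semantics.** "First frame spans 0.2–0.7" is read as
  the first frame's vertical *extent* mapping onto [0.2, 0.7]; with
  the open-lid apex at the top of its arch this makes an incomplete
  blink that moves 0.244 from 0.7 bottom out at 0.456, which is the
  arithmetic the worked examples use. The center-map reading is the
  documented fallback for flat first frames.
* **The 0.25–0.3 gap.** Closed requires `d < 0.25`; incomplete
  requires `min(d) > 0.3`. A minimum inside [0.25, 0.3] is treated as
  "no closed phase, but not incomplete" (the gap rule) and the label
  stays normal; both thresholds are config keys.
* **Detection span vs. displacement span.** The candidate span stops
  where the *intensity* excursion falls to 10 %; since covered eye
  area is a nonlinear function of lid position, this span is a few
  frames shorter than the displacement-based blink span. The 12-frame
  pad restores the context, and all phase durations are measured on
  the displacement trace, so the discrepancy does not propagate.

## The synthetic generator

`render_blink_video()` draws a bright skin canvas (180 of 255) with a
dark eye blob (40) under a quadratic upper-lid arch (curvature 0.02
px/px², 40 px aperture, 160 × 120 px scene) whose apex follows the
composed blink trajectory; a 3 px dark lash line rides on the arch so
the lid margin stays visible at full closure, as real lashes do.
Gaussian sensor noise and sinusoidal illumination flicker are added
per pixel; the same seed gives bit-identical frames, and exact ground
truth (apex row, normalized displacement, phase label per frame) is
returned alongside.

The default closing/opening profile is **contact easing**
(`s(u) = 1 − cos(πu/2)`): the lid leaves the open position smoothly
but meets the closure point at full speed, the way a lid stops on
contact with the lower lid. A symmetric raised-cosine profile was
considered and rejected as the default: easing into closure spends
about 20 % of each moving phase inside the 0.2–0.25 displacement
band, which inflates the measured Complete Closed phase so much that
a 30 ms closed phase (a value the worked examples need) becomes
unreachable for any segment durations. `"cosine"` and `"linear"`
profiles remain available.

Ground truth carries two phase descriptions: the per-frame trajectory
labels (which segment generated the frame) and the displacement-rule
durations (applying the 0.25/0.3 segmentation to the exact
displacement, in an independent code path). Recovery tests compare
the pipeline against the latter — comparing a threshold-defined
estimate against trajectory segment durations would mix two different
definitions of "phase".

The standard fixtures emulate the four pattern classes, with segment
durations solved so the displacement-rule durations land on the
narrated values: NORMAL closes 143 ms / holds 4 ms / opens 267 ms,
measuring ≈ 116/30/216 ms (total 362 ms, closed ratio ≈ 8.3 %);
INCOMPLETE reaches amplitude 0.488 (minimum displacement ≈ 0.456)
over ≈ 162 ms; PROLONGED measures ≈ 125/208/192 ms (closed ratio
≈ 40 %); CONSECUTIVE starts a second, complete blink 810 ms in, while
the first (incomplete, amplitude 0.6) is still reopening.

**What the generator does not emulate:** eyelashes as individual
structures, iris/pupil contrast, specular reflections, head motion,
occlusion by glasses or hair, and compression artifacts. Passing
tests therefore demonstrate the correctness of the algorithmic chain
under controlled contrast and noise, not robustness to every artifact
of consumer video; on real footage the histogram-valley threshold and
the motion-blob ROI are the stages most exposed to those effects.

## Problem sizes used in the test suite

Fixtures are 2 s at 240 fps (480 frames, 160 × 120 px). The
parameter-recovery sweep spans closing duration {60…180 ms} × closed
hold {0…250 ms} × amplitude {1.0, 0.85, 0.45} × 3 noise seeds at
noise SD 3, about 1.2 s of video each. The outlier-removal oracle
uses 100 randomized instances of ≤ 15 points (at most 4 planted
outliers, each displaced by more than 10 × tol, and at least 7 clean
points so the instance is well posed); the event-simulation oracle
uses 1000 random 50-step traces compared exactly.

## Known limitations

* Video containers (MP4/AVI) are not decoded; inputs are lossless
  frame directories (PNG/TIFF with an fps sidecar). Decode first,
  e.g. `ffmpeg -i clip.mp4 frames/f%06d.png`.
* One eye region per video; no face detection or multi-face handling.
* The displacement thresholds 0.25/0.3 are absolute on the 0.2–0.7
  scale and do not rescale when a blink's open level differs from
  0.7.
* Prolonged blinking is reported through its long closed ratio, not
  as a separate label, since no duration threshold defines it.
* Blink rate and group-level statistics are descriptive only; no
  clinical inference is attempted.

## A worked run

```{r example, eval = FALSE}
fx <- standard_fixtures()
fit <- blink_analysis(fx$PROLONGED$seq)
summary(fit)
rec <- fit$records[[1]]
render_projection(rec$matrix, "prolonged.png")
```
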
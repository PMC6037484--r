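---
title: "Motion correction of time-tagged FLIM data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion correction of time-tagged FLIM data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Laser-scanning FLIM builds an image one pixel at a time: a 256 × 256 frame
at a 1 kHz line rate takes a quarter of a second, and a usable lifetime
image accumulates tens of such frames. Any sample motion during that time
— heartbeat (~6 Hz in an anaesthetised mouse), respiration (~1 Hz),
peristalsis — does not simply translate frames: it *distorts* them,
because different image rows are acquired at different times. flimreg
estimates that intra-frame motion directly from the raster geometry of
time-tagged (TTTR) photon data, and rebuilds an undistorted FLIM image by
putting every photon back where it came from.

## Data model

A TTTR stream is a time-ordered sequence of photon events (macro time in
coarse clock ticks, micro time in sub-nanosecond bins since the last
excitation pulse, spectral channel) interleaved with frame-start and line
start/end markers. From the markers alone we recover the raster timing
(`infer_scan_timing()`): the active line duration `t_line`, the line
start-to-start period, and the frame period; the pixel dwell is
`t_pixel = t_line / n_x`. Photons are binned into pixels by elapsed time
within their line (half-open bins, 0-based coordinates); photons arriving
during retrace are counted and set aside. The acquisition time of pixel
`(x, y, z)` relative to its frame start is the raster-time map

    t(x, y, z) = x * t_pixel + y * (t_line + t_interline) + z * t_slice.

For multi-slice stacks we read the per-slice term as the slice
start-to-start period measured from the markers (the frame-period reading
would only be correct for a single-slice scan).

On disk, streams travel in an open single-file Parquet container (one
events table sorted by macro time plus the geometry attributes as file
metadata); intensity series travel as multi-page float TIFF in TCZYX page
order with an XML metadata companion.

## Motion model and estimation

Sample motion during a frame is modelled as a piecewise-linear
displacement field: `n` knots `r(i)` (pixels, 2D or 3D) equally spaced
over the frame period, both endpoints included, with linear interpolation
in between. The knots of every frame are estimated against a
user-selectable reference frame by an inverse-compositional Lucas-Kanade
fit: the warped frame samples the recorded image at
`(x, y, z) + D(t(x, y, z))` (bi/trilinear interpolation), and the summed
squared residual against the template is minimised over the knot vector
`p = (rx(1), ry(1)[, rz(1)], rx(2), ...)`.

Because the warp is a pure per-pixel translation, the steepest-descent
images `grad(T) * dD/dp` and the Gauss-Newton Hessian
`H = sum (grad(T) dD/dp)' (grad(T) dD/dp)` depend only on the template and
are precomputed once per reference. Each pixel's displacement involves at
most the two knots bracketing its acquisition time, so under the
interleaved parameter ordering H is banded with `2d - 1` super-diagonals
(6 non-zero diagonals at or above the main one for 3D); all linear solves
go through a banded Cholesky factorisation, which is what makes large 3D
stack-series problems tractable.

Steps are taken with a trust-region scheme: the quadratic model is
minimised within a radius Δ (Newton step if interior, otherwise the
boundary solution of the secular equation), and Δ adapts to the agreement
between predicted and actual reduction (shrink ×0.25 below ratio 0.25,
grow ×2 above 0.75, radius capped at the image diagonal, initial radius
`sqrt(m)` px). Iteration stops when the error change falls below a
relative tolerance of 1e-6 (the error is computed on intensity-normalised
images, so an absolute threshold would be scale-dependent) or after 200
iterations; non-convergence returns the best result found, flagged.

### Numerical choices that matter

* **Out-of-bounds samples.** Warped samples falling outside the recorded
  frame are excluded from the error and gradient sums (clamping would
  bias the fit toward the edges). Excluding them, however, makes the raw
  summed error smaller for absurdly large displacements simply because
  fewer pixels are counted; both the choice among starting candidates and
  the trust-region accept/reject test therefore use the *mean* residual
  per valid voxel, which removes that degenerate attractor.
* **Quality metric.** The per-frame correlation `r` with the reference is
  computed over the full template support with unsampled voxels reading
  zero. Scoring only the surviving overlap systematically flatters failed
  fits (a warp that throws away half the frame can correlate well on the
  remainder); the zero-filled metric matches what the reconstructed,
  gap-containing image actually looks like. `r` is reported on the
  smoothed images used for estimation (the stable basis at TCSPC count
  rates); the unsmoothed value `r_raw` is kept alongside. The sweep
  harness goes one step further and correlates the *photon-reassigned*
  frame (`reassigned_frame_images()`) with the reference: the estimation
  warp interpolates and so can stretch or duplicate scan lines to
  resemble the template even when the motion was not recovered, whereas
  reassignment conserves photons, so unrecovered motion shows up honestly
  as gaps and pile-up.
* **Initialisation.** Three candidate starts are evaluated and the one
  with the lowest mean residual wins: the null displacement, a rigid
  shift from windowed phase correlation applied to every knot, and (in
  series fitting) the previous frame's trace. Phase correlation itself
  runs twice — the integer part of the first pass is removed by a
  circular shift and the sub-pixel residual re-estimated — because the
  3-point parabolic peak interpolation is only accurate near zero shift
  under a Hanning window.
* **Coarse-to-fine knots.** By default `fit_frame_series()` first fits a
  half-resolution knot set and hands the resampled trace to the full
  model (non-final stages at a relaxed tolerance of 1e-4). A 20-knot fit
  of a 6 Hz oscillation started from rest otherwise falls into aliased
  local minima on a non-trivial fraction of frames.
* **Smoothing.** Frames and template are pre-smoothed for estimation only
  with an elliptical Gaussian: user-set sigma along the fast axis, 1 px
  along the slow axis. The package default is `sigma_x = 2`; the sweep
  harness uses 4, the upper end of the 2–4 px range that works well,
  because the default simulation's per-frame SNR (~1.3 counts/pixel) is
  low enough that the extra capture range decides convergence on fast
  large-amplitude cells.

## Reconstruction

The estimation warp is deliberately not intensity-preserving. The final
data are instead rebuilt by per-photon reassignment: each photon recorded
at pixel `(x, y, z)` at macro time `t` moves to the rounded coordinate
`(x, y, z) - D(t)` under its frame's fitted trace, keeping its micro time
and channel, so photon statistics are untouched. Photons landing outside
the image are dropped and counted; frames whose correlation falls below a
threshold (0.8 is a practical choice) are excluded entirely. Because
motion makes the effective dwell time uneven, the same reassignment is
applied to each scan pixel's dwell `t_pixel`, yielding an
integration-time image used to normalise intensity afterwards. A full
accounting (input = kept + unassigned + excluded + out-of-bounds) is
attached to every reconstruction. Pre-binned intensity time series are
corrected analogously with forward voxel deposition and dwell
normalisation, all channels sharing one trace per time point.

Rounding to the nearest integer pixel (ties up) is our choice — photons
are indivisible counts and the alternative, splitting photons across
pixels, would alter the Poisson statistics downstream lifetime fitting
relies on.

## The simulator

`simulate_tttr()` generates the test conditions used throughout: a
256 × 256 raster at a 1 kHz line rate with duty cycle 0.33, the
inter-frame gap equal to the interline gap, an 80 MHz excitation clock, a
1 MHz average detected count rate, and sinusoidal sample motion
`D(t) = A sin(2 pi f t)` at an angle θ to the fast axis. Per pixel the
photon count is Poisson with mean proportional to the bilinearly sampled
(edge-clamped) moving scene; photon macro times spread evenly across the
dwell; micro times are an exponential decay (default lifetime 2 ns) plus
a Gaussian instrument response (mean 1 ns, width 100 ps), wrapped at the
repetition period as TCSPC hardware does. The bundled procedural scene
(Gaussian blobs over filaments) stands in for a high-SNR tissue image so
no external data are needed.

What the simulator does *not* emulate — detector dead time and
afterpulsing, bidirectional scanning, rotation or non-rigid deformation,
axial (z) motion in the photon stream, autofluorescence background —
bounds what passing tests demonstrate: correction of in-plane translational
motion under Poisson statistics, not every artefact of real intravital
data.

The sweep harness registers simulated frames against one additional
motion-free simulated frame (a quiescent moment of the same acquisition).
That keeps the ground truth well defined: with a clean reference the
estimator's target is exactly the negated generating displacement at each
pixel's acquisition time, and the reported RMSE is computed against it.
Using a distorted member of the series as reference (as one would on real
data) leaves the truth defined only up to the reference's own distortion;
we measured materially worse and harder-to-interpret scores that way.

## Quantification

* **Phasor.** First-harmonic coordinates
  `g = Σ I cos(2πt/T) / Σ I`, `s` with sine, bin centres, zero-intensity
  pixels masked. Gating uses 5 × 5 uniform-smoothed coordinate maps
  (NA-aware at edges) and boundary-inclusive point-in-polygon selection.
  With the wrapped decay tail included, noiseless mono-exponential pixels
  sit on the universal semicircle to discretisation accuracy.
* **Complex-donor FRET.** The ECFP-like donor is a fixed two-conformer
  bi-exponential (defaults τ1 = 1330 ps, τ2 = 3350 ps, β1 = 0.434); FRET
  shortens each conformer lifetime to `τi (1 - Ei)` with the two
  efficiencies linked through `E1/(1-E1) = (τ1/τ2) E2/(1-E2)`. The decay
  printed with a bare `exp(τ(1-E))` in some descriptions is implemented
  as `exp(-t/(τ(1-E)))`, the only physically meaningful reading. The
  image model `I(t) = I (γH F(t;E1H) + (1-γH) F(t;E1L))` is fitted with
  global efficiencies and per-pixel fractions: the efficiencies are
  optimised by Poisson maximum likelihood on all masked pixels while each
  pixel's two non-negative amplitudes are profiled out analytically, so
  γH = aH/(aH+aL) lands in [0, 1] by construction (the unconstrained
  linear solution is reported alongside). When only one conformation is
  present the second efficiency is unidentifiable; `fix_efficiencies`
  skips the global stage for that case.
* **Single-exponential lifetimes.** Poisson-MLE over the binned decay
  with the model convolved with a Gaussian IRF (exponentially modified
  Gaussian, computed in log space) and wrapped at the repetition period;
  optional 3 × 3 binning before per-pixel fits.
* **Spectral unmixing.** Reference patterns are 4-component exponential
  fits (non-negative amplitudes by NNLS, lifetimes optimised) of summed
  region decays per channel, normalised to unit total; per-pixel
  abundances solve the stacked time-by-channel non-negative least-squares
  problem.

## Problem sizes used by the test-suite

Unit tests run on 8–64 px scenes in seconds. The performance sweep runs
the reference simulation conditions at 256 × 256 with 10 frames per cell
on a 4 × 4 amplitude–frequency grid at 0° and 90°, about 15 s per cell;
the FRET recovery uses a 22 × 22 image at 500 photons/pixel and the
lifetime Monte Carlo 200 replicates of 1000 photons. These sizes were
chosen so the whole suite completes on a laptop-class single core while
still exercising the reference operating conditions.

## Known limitations

* Motion through the fitted warp is translational only; rotation, shear
  and non-rigid deformation are out of scope.
* In the uncorrectable regime (large, fast motion, especially along the
  slow axis) the fitted warp retains enough freedom to *partially* raise
  the estimation-basis correlation without recovering the true motion —
  whole scan lines can be remapped onto similar-looking template rows.
  The displacement RMSE against known motion (tens of pixels there) and
  the reassignment-based correlation expose this; `lk_fit$r` alone can
  overstate quality for badly failed frames, which is why the sweep and
  any threshold decision should use the reconstructed-frame correlation.
* Endpoint knots are supported by fewer pixels than interior knots and
  carry visibly larger uncertainty; fits are exact to a few tenths of a
  pixel at interior knots on noiseless data but roughly half a pixel at
  the frame boundaries.
* The estimator assumes the reference frame is representative; a
  reference chosen during strong motion degrades every fit against it.
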
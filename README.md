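# flimreg

Motion correction and quantification for laser-scanning fluorescence
lifetime imaging (FLIM) acquired as time-tagged time-resolved (TTTR)
photon streams — and for ordinary multi-channel intensity time series.

## The problem

A laser-scanning microscope acquires an image pixel by pixel, so sample
motion during a frame (heartbeat ~6 Hz, respiration ~1 Hz, peristalsis)
does not merely shift the image — it distorts it, because each scan line
is recorded at a different time. FLIM makes this worse: usable lifetime
images accumulate photons over many seconds, and discarding unstable
acquisitions is often not an option in intravital or clinical imaging.

flimreg estimates the motion *within* each frame directly from the raster
timing and corrects the photon data without altering its statistics. The
sample displacement during a frame is modelled as a piecewise-linear
field `D(t)` over scan time with `n` knots `r(i)`,

    D(t) = r(i) + (r(i+1) - r(i)) (t - t_i)(n-1)/t_frame,
    t(x, y, z) = x t_pixel + y (t_line + t_interline) + z t_slice,

and the knot vector `p = (rx(1), ry(1), rz(1), ..., rx(n), ry(n), rz(n))`
is fitted per frame by inverse-compositional Lucas-Kanade registration
against a reference frame: minimise `E(p) = Σ (Ĩ(x; p) - T(x))²` with a
trust-region scheme in which the steepest-descent images and the
Gauss-Newton Hessian `H = Σ (∇T ∂D/∂p)ᵀ(∇T ∂D/∂p)` are precomputed once.
Under the interleaved parameter ordering H is banded (6 non-zero upper
diagonals in 3D), so every solve uses a banded Cholesky factorisation.
Coarse shifts come from windowed phase correlation; fit quality per frame
is the correlation `r` with the reference, and frames below a threshold
(typically 0.8) are excluded. Corrected FLIM data are rebuilt by moving
each photon to `(x, y, z) - D(t)` and accumulating a dwell-time image for
intensity normalisation. A Monte-Carlo TTTR simulator generates
motion-distorted photon streams for validation, and the package also
quantifies the corrected data: phasor analysis with gating, complex-donor
FRET fraction fitting, single-exponential lifetime fitting, and
non-negative least-squares spectral unmixing.

## Worked example

Simulate a heartbeat-like distortion — 256 × 256 pixels, 1 kHz line rate,
duty cycle 0.33, 1 MHz count rate, sinusoidal motion of 10% of the field
of view at 6 Hz along the fast axis — and correct it:

```r
library(flimreg)

geom   <- default_scan_geometry()           # 256 x 256, 1 kHz, duty 0.33
scene  <- make_test_image(256, 256, seed = 42)
motion <- motion_spec(A = 0.10 * 256, f = 6, theta = 0)

stream <- simulate_tttr(scene, motion, emission_spec(), geom,
                        n_frames = 10, seed = 1)
still  <- simulate_tttr(scene, motion_spec(0, 0, 0), emission_spec(),
                        geom, n_frames = 1, seed = 2)

frames <- reconstruct_frames(stream, geom)
ref    <- reconstruct_frames(still, geom)[[1]]

series <- fit_frame_series(frames, geom, reference = ref,
                           n_knots = 20, sigma_x = 4)
series
#> lk_series: 10 frames, mean r = 0.9033 (10 converged)

flim <- reassign_photons(stream, lapply(series$fits, `[[`, "trace"),
                         geom, r_values = series$log$r, r_thresh = 0.8)
flim
#> flim_image: 256 x 256 x 1, 1 channel(s), 256 time bins
#>   photons kept 2178998 / 2528232 (unassigned 158, excluded 241876, oob 107200)
#>   excluded frames: 8
```

The mean frame-to-reference correlation rises from about 0.51 before
correction to 0.90 after (images are compared over the full frame, with
unsampled regions counting as empty). Eight of the ten fitted traces
agree with the generating sinusoid to better than one pixel RMS at the
pixel level; one frame fell below the 0.8 correlation threshold and its
photons were discarded wholesale — exactly what the threshold is for —
and one retained frame locked onto a partially wrong trace while still
correlating acceptably, a reminder that `r` is a quality screen, not a
guarantee. Every kept photon contributes exactly one count at its
corrected pixel; the dropped photons (out-of-bounds after correction,
retrace, excluded frame) are itemised in the accounting shown above. The
per-pixel decay histograms in `flim$histogram` then feed the analysis
functions, e.g. `phasor_transform(flim)` or `fit_lifetime_image(flim)`.

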
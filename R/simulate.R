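#' Sinusoidal (or custom) sample-motion specification
#'
#' The simulated sample motion is
#' `Dx(t) = A cos(theta) sin(2 pi f t)`, `Dy(t) = A sin(theta) sin(2 pi f t)`
#' with amplitude `A` in pixels, frequency `f` in Hz and angle `theta`
#' (degrees) from the fast scan axis. A custom displacement trace spanning
#' the acquisition can be supplied instead.
#'
#' @param A Amplitude in pixels (`>= 0`).
#' @param f Frequency in Hz (`>= 0`).
#' @param theta Angle from the fast axis in degrees.
#' @param custom Optional function `t_seconds -> cbind(Dx, Dy)` overriding
#'   the sinusoid.
#' @export
motion_spec <- function(A = 0, f = 0, theta = 0, custom = NULL) {
  if (A < 0 || f < 0) stop("amplitude and frequency must be non-negative")
  structure(list(A = A, f = f, theta = theta, custom = custom),
            class = "motion_spec")
}

#' Evaluate the true sample displacement of a motion spec
#' @param motion A [motion_spec()].
#' @param t_seconds Absolute acquisition times in seconds.
#' @return `length(t) x 2` matrix (Dx, Dy) in pixels.
#' @export
motion_displacement <- function(motion, t_seconds) {
  if (!is.null(motion$custom)) return(motion$custom(t_seconds))
  th <- motion$theta * pi / 180
  s <- motion$A * sin(2 * pi * motion$f * t_seconds)
  cbind(s * cos(th), s * sin(th))
}

#' Photon emission model for the simulator
#'
#' Micro times are drawn as the sum of an exponential decay (lifetime
#' `tau`) and a Gaussian instrument response (`irf_mu`, `irf_sigma`),
#' wrapped modulo the laser repetition period as in TCSPC hardware.
#'
#' @param tau Fluorescence lifetime in seconds (default 2 ns).
#' @param irf_mu,irf_sigma IRF centre and width in seconds (defaults
#'   1 ns and 100 ps).
#' @export
emission_spec <- function(tau = 2e-9, irf_mu = 1e-9, irf_sigma = 100e-12) {
  if (tau <= 0 || irf_sigma <= 0 || irf_mu < 0) {
    stop("emission parameters must be positive")
  }
  structure(list(tau = tau, irf_mu = irf_mu, irf_sigma = irf_sigma),
            class = "emission_spec")
}

#' Default simulated scan geometry
#'
#' The study conditions used throughout: 256 x 256 pixels, 1 kHz line rate
#' with a 0.33 duty cycle, inter-frame gap equal to the interline gap
#' (approximating a Leica SP8-style raster), 80 MHz repetition rate and a
#' 100 ns macro tick.
#'
#' @param n_x,n_y Image size in pixels.
#' @param line_rate Line start-to-start rate in Hz.
#' @param duty_cycle Active fraction of the line period.
#' @param macro_resolution Seconds per macro tick.
#' @param n_t Micro-time bins across the repetition period.
#' @param rep_period Laser repetition period in seconds.
#' @export
default_scan_geometry <- function(n_x = 256L, n_y = 256L, line_rate = 1000,
                                  duty_cycle = 0.33,
                                  macro_resolution = 1e-7,
                                  n_t = 256L, rep_period = 12.5e-9) {
  s2s <- 1 / (line_rate * macro_resolution)
  scan_geometry(
    n_x = n_x, n_y = n_y, n_z = 1L,
    t_line = duty_cycle * s2s, t_interline = (1 - duty_cycle) * s2s,
    macro_resolution = macro_resolution,
    micro_resolution = rep_period / n_t, rep_period = rep_period
  )
}

#' Intensity scale for a target average count rate
#'
#' Returns the factor `alpha` such that a simulation of `image` yields the
#' requested detector count rate averaged over wall time.
#'
#' @param image Reference intensity image (arbitrary units).
#' @param geom A [scan_geometry()].
#' @param count_rate Target photons per second (default 1e6).
#' @export
alpha_for_count_rate <- function(image, geom, count_rate = 1e6) {
  t_frame_s <- geom$t_frame * geom$macro_resolution
  count_rate * t_frame_s / sum(image)  # photons/frame = alpha * sum(I)
}

#' Procedural reference image for simulations
#'
#' A built-in high-SNR test scene: smooth Gaussian blobs over faint
#' filamentous structures on a low background, mimicking the broad
#' intensity structure of tissue autofluorescence. Values in `[0, 1]`.
#'
#' @param n_y,n_x Image size.
#' @param seed RNG seed for the procedural texture.
#' @param n_blobs,n_filaments Feature counts.
#' @return `n_y x n_x` matrix.
#' @export
make_test_image <- function(n_y = 256L, n_x = 256L, seed = 42L,
                            n_blobs = 18L, n_filaments = 6L) {
  withr_seed(seed, {
    img <- matrix(0, n_y, n_x)
    xs <- seq_len(n_x); ys <- seq_len(n_y)
    for (i in seq_len(n_blobs)) {
      cx <- stats::runif(1, 1, n_x); cy <- stats::runif(1, 1, n_y)
      sx <- stats::runif(1, 4, 14); sy <- stats::runif(1, 4, 14)
      amp <- stats::runif(1, 0.3, 1)
      img <- img + amp * outer(exp(-0.5 * ((ys - cy) / sy)^2),
                               exp(-0.5 * ((xs - cx) / sx)^2))
    }
    fil <- matrix(0, n_y, n_x)
    for (i in seq_len(n_filaments)) {
      px <- stats::runif(1, 1, n_x); py <- stats::runif(1, 1, n_y)
      ang <- stats::runif(1, 0, 2 * pi)
      for (s in seq_len(4 * max(n_x, n_y))) {
        ang <- ang + stats::rnorm(1, 0, 0.08)
        px <- px + cos(ang); py <- py + sin(ang)
        ix <- round(px); iy <- round(py)
        if (ix < 1 || ix > n_x || iy < 1 || iy > n_y) break
        fil[iy, ix] <- fil[iy, ix] + 1
      }
    }
    fil <- array(fil, dim = c(n_y, n_x, 1))
    k <- gauss_kernel1d(1.5)
    fil <- convolve_dim(convolve_dim(fil, k, 1), k, 2)[, , 1]
    img <- 0.08 + img / max(img) + 0.6 * fil / max(max(fil), 1e-12)
    img / max(img)
  })
}

# Evaluate an expression with a temporarily seeded RNG, restoring the
# caller's RNG state afterwards.
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Bilinear sampling with edge clamping (the simulator's reading of the
# reference scene outside its support).
interp_clamped <- function(img, xq, yq) {
  n_y <- nrow(img); n_x <- ncol(img)
  xq <- pmin(pmax(xq, 0), n_x - 1)
  yq <- pmin(pmax(yq, 0), n_y - 1)
  x0 <- pmin(floor(xq), n_x - 2); y0 <- pmin(floor(yq), n_y - 2)
  if (n_x == 1) x0 <- 0
  if (n_y == 1) y0 <- 0
  fx <- xq - x0; fy <- yq - y0
  at <- function(xx, yy) img[xx * n_y + yy + 1]
  v00 <- at(x0, y0); v10 <- at(pmin(x0 + 1, n_x - 1), y0)
  v01 <- at(x0, pmin(y0 + 1, n_y - 1))
  v11 <- at(pmin(x0 + 1, n_x - 1), pmin(y0 + 1, n_y - 1))
  (v00 * (1 - fx) + v10 * fx) * (1 - fy) + (v01 * (1 - fx) + v11 * fx) * fy
}

#' Simulate a motion-distorted TTTR event stream
#'
#' Monte-Carlo generator of 2D time-tagged photon data: the scanner
#' rasters over a reference scene `I_S` that is translating under the
#' sample-motion model, each pixel's photon count is drawn from a Poisson
#' distribution with mean `alpha * I_S(x + Dx(t), y + Dy(t))` (bilinear,
#' edge-clamped), photon macro times are spaced evenly across the pixel
#' dwell, micro times follow the emission model wrapped at the repetition
#' period, and frame/line markers are inserted per the raster timing.
#' Identical seeds give bit-identical streams.
#'
#' @param ref_image `n_y x n_x` reference intensity (arbitrary units).
#' @param motion A [motion_spec()].
#' @param emission An [emission_spec()].
#' @param geom A [scan_geometry()] (2D).
#' @param n_frames Number of frames to generate (default 50).
#' @param seed Integer RNG seed.
#' @param alpha Intensity scale (counts per pixel per unit `I_S`); default
#'   targets a 1 MHz average count rate via [alpha_for_count_rate()].
#' @return A [tttr_stream()] with geometry attached and attribute
#'   `motion` (the generating [motion_spec()]).
#' @export
simulate_tttr <- function(ref_image, motion, emission, geom,
                          n_frames = 50L, seed = 1L, alpha = NULL) {
  if (!all(is.finite(ref_image))) stop("reference image must be finite")
  n_x <- geom$n_x; n_y <- geom$n_y
  if (nrow(ref_image) != n_y || ncol(ref_image) != n_x) {
    stop("reference image shape does not match the scan geometry")
  }
  if (is.null(alpha)) {
    alpha <- 1e6 * geom$t_frame * geom$macro_resolution / sum(ref_image)
  }
  s2s <- geom$t_line + geom$t_interline
  xs <- rep(seq_len(n_x) - 1, times = n_y)        # raster order: x fastest
  ys <- rep(seq_len(n_y) - 1, each = n_x)
  pix_start_rel <- ys * s2s + xs * geom$t_pixel
  n_t <- max(1L, round(geom$rep_period / geom$micro_resolution))

  withr_seed(seed, {
    ph_t <- vector("list", n_frames)
    ph_u <- vector("list", n_frames)
    mk_t <- vector("list", n_frames)
    mk_k <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      t0 <- (f - 1) * geom$t_frame
      t_mid_s <- (t0 + pix_start_rel + 0.5 * geom$t_pixel) *
        geom$macro_resolution
      D <- motion_displacement(motion, t_mid_s)
      lam <- alpha * interp_clamped(ref_image, xs + D[, 1], ys + D[, 2])
      N <- stats::rpois(length(lam), lam)
      tot <- sum(N)
      if (tot > 0) {
        rep_idx <- rep.int(seq_along(N), N)
        within <- (sequence(N) - 0.5) / rep.int(N, N)
        t_ph <- round(t0 + pix_start_rel[rep_idx] + within * geom$t_pixel)
        micro_s <- (stats::rexp(tot, rate = 1 / emission$tau) +
                      stats::rnorm(tot, emission$irf_mu, emission$irf_sigma)) %%
          geom$rep_period
        bins <- pmin(floor(micro_s / geom$micro_resolution), n_t - 1)
        ph_t[[f]] <- t_ph
        ph_u[[f]] <- as.integer(bins)
      } else {
        ph_t[[f]] <- numeric(0)
        ph_u[[f]] <- integer(0)
      }
      line_starts <- t0 + (seq_len(n_y) - 1) * s2s
      mk_t[[f]] <- c(t0, as.vector(rbind(line_starts,
                                         line_starts + geom$t_line)))
      mk_k[[f]] <- c(MARKER_FRAME_START,
                     rep(c(MARKER_LINE_START, MARKER_LINE_END), n_y))
    }
    photons <- data.frame(macro_time = unlist(ph_t),
                          micro_time = unlist(ph_u),
                          channel = 0L)
    markers <- data.frame(macro_time = unlist(mk_t),
                          kind = as.integer(unlist(mk_k)))
    stream <- tttr_stream(photons, markers, geometry = geom)
    attr(stream, "motion") <- motion
    attr(stream, "alpha") <- alpha
    stream
  })
}

#' True relative displacement seen by the estimator
#'
#' The registration estimates, for each output pixel, the shift that maps
#' the recorded frame back onto the reference; for a scene translating by
#' `D_true` this is `-D_true` evaluated at the pixel's acquisition time
#' (when the reference itself is motion-free). Used to score estimated
#' traces against the generating motion.
#'
#' @param motion A [motion_spec()].
#' @param geom A [scan_geometry()].
#' @param frame 0-based frame index.
#' @return `[n_y, n_x]` x 2 matrix (as `n_pix x 2`) of expected estimated
#'   displacements at every pixel, raster (column-major y-fastest) order.
#' @export
expected_estimated_displacement <- function(motion, geom, frame) {
  tpx <- as.vector(pixel_time_array(geom)) + frame * geom$t_frame
  -motion_displacement(motion, (tpx + 0.5 * geom$t_pixel) *
                         geom$macro_resolution)
}

#' Score estimated traces against the generating motion
#'
#' Root-mean-square error, over frames and pixels, between the estimated
#' displacement evaluated at each pixel's scan time and the expected value
#' from the generating motion (see
#' [expected_estimated_displacement()]). The error is the Euclidean
#' distance of the 2D displacement vectors.
#'
#' @param fits List of `lk_fit` (or an `lk_series`).
#' @param motion A [motion_spec()].
#' @param geom A [scan_geometry()].
#' @param stride Pixel subsampling stride for speed (default 7).
#' @export
trace_rmse <- function(fits, motion, geom, stride = 7L) {
  if (inherits(fits, "lk_series")) fits <- fits$fits
  tpx <- as.vector(pixel_time_array(geom))
  sel <- seq(1, length(tpx), by = stride)
  sq <- 0; nn <- 0
  for (f in seq_along(fits)) {
    est <- displacement_at(fits[[f]]$trace, tpx[sel])
    truth <- -motion_displacement(
      motion, (tpx[sel] + (f - 1) * geom$t_frame + 0.5 * geom$t_pixel) *
        geom$macro_resolution)
    sq <- sq + sum((est[, 1] - truth[, 1])^2 + (est[, 2] - truth[, 2])^2)
    nn <- nn + length(sel)
  }
  sqrt(sq / nn)
}

#' Correction-performance sweep over motion amplitude and frequency
#'
#' The simulation harness behind the performance maps: for each
#' `(A, f)` cell a motion-free reference frame and `n_frames` distorted
#' frames are simulated, the full estimation pipeline is run against the
#' reference, and the mean corrected and uncorrected frame correlations
#' plus the displacement RMSE against the generating motion are recorded.
#' Deterministic for a fixed `seed`.
#'
#' @param ref_image Reference scene (`n_y x n_x`, values in `[0, 1]`).
#' @param A_grid Amplitudes as fractions of the field of view (`n_x`).
#' @param f_grid Frequencies in Hz.
#' @param theta Motion angle from the fast axis, degrees.
#' @param geom A [scan_geometry()].
#' @param n_frames Frames per cell (default 10).
#' @param seed Base RNG seed; each cell derives its own sub-seed.
#' @param emission An [emission_spec()].
#' @param n_knots,sigma_x,schedule,control Passed to [fit_frame_series()].
#' @return data.frame with columns `A_fov`, `A_px`, `f`, `theta`,
#'   `mean_r_uncorrected`, `mean_r_corrected`, `rmse_px`.
#' @export
sweep_correction_performance <- function(ref_image, A_grid, f_grid, theta,
                                         geom, n_frames = 10L, seed = 1L,
                                         emission = emission_spec(),
                                         n_knots = 20L, sigma_x = 2,
                                         schedule = if (n_knots >= 8)
                                           round(n_knots / 2),
                                         control = list()) {
  if (!length(A_grid) || !length(f_grid)) stop("empty sweep grid")
  grid <- expand.grid(A_fov = A_grid, f = f_grid)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    A_px <- grid$A_fov[i] * geom$n_x
    cell_seed <- (seed * 1000L + i * 7L + round(theta)) %% .Machine$integer.max
    res <- tryCatch(
      correction_trial(ref_image, motion_spec(A_px, grid$f[i], theta),
                       geom, n_frames, cell_seed, emission,
                       n_knots, sigma_x, schedule, control),
      error = function(e) {
        message(sprintf("sweep cell A=%.3g f=%.3g failed: %s",
                        grid$A_fov[i], grid$f[i], conditionMessage(e)))
        list(r_corr = NA_real_, r_unc = NA_real_, rmse = NA_real_)
      })
    rows[[i]] <- data.frame(
      A_fov = grid$A_fov[i], A_px = A_px, f = grid$f[i], theta = theta,
      mean_r_uncorrected = res$r_unc, mean_r_corrected = res$r_corr,
      rmse_px = res$rmse
    )
  }
  do.call(rbind, rows)
}

# One sweep cell: simulate, register, score. Corrected frames are scored
# as their photon-reassigned reconstructions (the image the user keeps),
# not as the smooth estimation warp, which can overstate quality for
# uncorrectable motion.
correction_trial <- function(ref_image, motion, geom, n_frames, seed,
                             emission, n_knots, sigma_x, schedule, control) {
  still <- simulate_tttr(ref_image, motion_spec(0, 0, 0), emission, geom,
                         n_frames = 1L, seed = seed)
  moving <- simulate_tttr(ref_image, motion, emission, geom,
                          n_frames = n_frames, seed = seed + 1L)
  ref_frame <- reconstruct_frames(still, geom)[[1]]
  frames <- reconstruct_frames(moving, geom)
  series <- fit_frame_series(frames, geom, reference = ref_frame,
                             n_knots = n_knots, sigma_x = sigma_x,
                             schedule = schedule, control = control)
  model <- series$model
  r_unc <- vapply(frames, function(fr) {
    fr_s <- smooth_fast_axis(fr, sigma_x) / model$norm
    frame_correlation(fr_s, model$template)
  }, numeric(1))
  corrected <- reassigned_frame_images(moving,
                                       lapply(series$fits, `[[`, "trace"),
                                       geom)
  r_corr <- vapply(corrected, function(fr) {
    fr_s <- smooth_fast_axis(fr, sigma_x) / model$norm
    frame_correlation(fr_s, model$template)
  }, numeric(1))
  list(
    r_corr = mean(r_corr),
    r_unc = mean(r_unc),
    rmse = trace_rmse(series, motion, geom),
    series = series
  )
}

#' Amplitude spectrum of an estimated displacement series
#'
#' Resamples the per-frame piecewise-linear traces onto the uniform knot
#' grid (`n - 1` samples per frame period), concatenates them across
#' frames and returns the one-sided FFT amplitude spectrum per axis.
#'
#' @param traces List of per-frame [displacement_trace()] (or an
#'   `lk_series`).
#' @param frame_period_s Frame start-to-start period in seconds.
#' @return list: `frequency` (Hz), `amplitude` (matrix, frequencies x d),
#'   `peak_frequency` (per axis, excluding the DC bin).
#' @export
amplitude_spectrum <- function(traces, frame_period_s) {
  if (inherits(traces, "lk_series")) {
    traces <- lapply(traces$fits, `[[`, "trace")
  }
  if (inherits(traces, "displacement_trace")) traces <- list(traces)
  if (length(traces) < 2) stop("insufficient data: need at least 2 frames")
  n <- traces[[1]]$n; d <- traces[[1]]$d
  tf <- traces[[1]]$t_frame
  tt <- seq(0, tf, length.out = n)[-n]            # drop the shared endpoint
  series <- do.call(rbind, lapply(traces, displacement_at, t = tt))
  N <- nrow(series)
  dt <- frame_period_s / (n - 1)
  nf <- N %/% 2 + 1
  amp <- apply(series, 2, function(x) {
    (2 / N) * Mod(stats::fft(x - mean(x)))[seq_len(nf)]
  })
  amp[1, ] <- 0                                    # mean removed: DC is 0
  freq <- (seq_len(nf) - 1) / (N * dt)
  pk <- apply(amp[-1, , drop = FALSE], 2, which.max)
  list(frequency = freq, amplitude = amp, peak_frequency = freq[pk + 1])
}

#' Peak-to-peak displacement statistics
#'
#' The per-frame displacement range (max - min of the knots, per axis),
#' aggregated as mean and standard deviation over the series.
#'
#' @param traces List of [displacement_trace()] (or an `lk_series`).
#' @return list: `per_frame` (frames x d matrix), `mean`, `sd` (per axis).
#' @export
peak_to_peak <- function(traces) {
  if (inherits(traces, "lk_series")) {
    traces <- lapply(traces$fits, `[[`, "trace")
  }
  if (inherits(traces, "displacement_trace")) traces <- list(traces)
  if (!length(traces)) stop("empty trace list")
  pf <- do.call(rbind, lapply(traces, function(tr) {
    apply(tr$knots, 2, function(k) max(k) - min(k))
  }))
  list(per_frame = pf, mean = colMeans(pf), sd = apply(pf, 2, stats::sd))
}
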
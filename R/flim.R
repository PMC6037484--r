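# Log-density of the exponentially modified Gaussian: the convolution of an
# exponential decay (lifetime tau) with a Gaussian IRF (mu, sigma). With
# `rep_period` set, the density is wrapped: photons from earlier excitation
# cycles fold into the current one, as in TCSPC acquisition.
emg_log_density <- function(t, tau, mu, sigma) {
  lam <- 1 / tau
  u <- (mu + lam * sigma^2 - t) / (sqrt(2) * sigma)
  log(lam) + lam * (mu - t) + 0.5 * (lam * sigma)^2 +
    stats::pnorm(-u * sqrt(2), log.p = TRUE)
}

emg_density <- function(t, tau, mu, sigma, rep_period = NULL, n_wrap = 3L) {
  d <- exp(emg_log_density(t, tau, mu, sigma))
  if (!is.null(rep_period)) {
    for (j in seq_len(n_wrap)) {
      d <- d + exp(emg_log_density(t + j * rep_period, tau, mu, sigma))
    }
  }
  d
}

# Expected bin contents (per unit amplitude) for a sum of exponential decay
# components convolved with a Gaussian IRF, evaluated at bin centres.
# amplitudes are the t = 0 decay amplitudes, so each component contributes
# area amplitude * tau (the convolution of a unit-area IRF preserves area).
decay_model_curve <- function(t_centers, amplitudes, lifetimes,
                              irf_mu, irf_sigma, rep_period = NULL) {
  stopifnot(length(amplitudes) == length(lifetimes))
  rowSums(vapply(seq_along(lifetimes), function(i) {
    amplitudes[i] * lifetimes[i] *
      emg_density(t_centers, lifetimes[i], irf_mu, irf_sigma, rep_period)
  }, numeric(length(t_centers))))
}

#' Phasor transform of FLIM data
#'
#' Maps each pixel's decay histogram to phasor coordinates at the first
#' harmonic of the laser repetition rate:
#' `g = sum I(t) cos(2 pi t / T) / sum I(t)` and likewise `s` with sine,
#' with `t` at bin centres. Noiseless mono-exponential decays (with the
#' wrapped tail included) lie on the universal semicircle
#' `(g - 1/2)^2 + s^2 = 1/4`. Zero-intensity pixels are masked (NA).
#' Smoothed copies of the coordinate maps (5 x 5 uniform kernel) are kept
#' for display and gating; the raw coordinates are untouched.
#'
#' @param x A `flim_image`, or an array whose last dimension is micro time
#'   (e.g. `[n_y, n_x, n_t]`), assumed to span one repetition period.
#' @param rep_period Repetition period `T` in seconds (defaults to the
#'   geometry carried by a `flim_image`).
#' @param n_bins Phasor-histogram resolution (default 256).
#' @return Object of class `phasor_map`: `g`, `s` (arrays over pixels),
#'   `g_smooth`, `s_smooth`, `intensity`, `histogram` (`n_bins x n_bins`,
#'   intensity-weighted, s rows x g columns over `[0, 1]^2`), `omega`.
#' @export
phasor_transform <- function(x, rep_period = NULL, n_bins = 256L) {
  if (inherits(x, "flim_image")) {
    if (is.null(rep_period)) rep_period <- x$geometry$rep_period
    h <- x$histogram               # [y, x, z, ch, t] -> sum channels
    d <- dim(h)
    arr <- array(h, dim = c(d[1], d[2], d[3] * d[4], d[5]))
    arr <- apply(arr, c(1, 2, 4), sum)   # [y, x, t]
  } else {
    arr <- x
  }
  if (is.null(rep_period)) stop("rep_period must be supplied")
  nd <- length(dim(arr))
  if (is.null(dim(arr))) arr <- array(arr, dim = c(1, 1, length(arr)))
  if (nd == 2) arr <- array(arr, dim = c(dim(arr)[1], 1, dim(arr)[2]))
  dims <- dim(arr)
  nt <- dims[length(dims)]
  if (nt < 2) stop("need at least 2 micro-time bins")
  tc <- (seq_len(nt) - 0.5) * rep_period / nt
  w <- 2 * pi / rep_period
  m <- matrix(arr, ncol = nt)
  inten <- rowSums(m)
  g <- as.numeric(m %*% cos(w * tc))
  s <- as.numeric(m %*% sin(w * tc))
  ok <- inten > 0
  g[ok] <- g[ok] / inten[ok]; s[ok] <- s[ok] / inten[ok]
  g[!ok] <- NA_real_; s[!ok] <- NA_real_
  pix_dims <- dims[-length(dims)]
  G <- array(g, dim = pix_dims); S <- array(s, dim = pix_dims)
  I <- array(inten, dim = pix_dims)

  gs <- smooth_map_uniform(G, 5L); ss <- smooth_map_uniform(S, 5L)
  hist <- phasor_histogram(g, s, inten, n_bins)
  structure(list(g = G, s = S, g_smooth = gs, s_smooth = ss, intensity = I,
                 histogram = hist, omega = w, rep_period = rep_period),
            class = "phasor_map")
}

# NA-aware uniform k x k smoothing of a 2D (or flat 3D) map.
smooth_map_uniform <- function(map, k = 5L) {
  dims <- dim(map)
  m2 <- array(map, dim = c(dims[1], prod(dims[-1]), 1))
  w <- array(as.numeric(is.finite(m2)), dim = dim(m2))
  m0 <- m2; m0[!is.finite(m0)] <- 0
  kern <- rep(1 / k, k)
  num <- convolve_dim(convolve_dim(m0, kern, 1), kern, 2)
  den <- convolve_dim(convolve_dim(w, kern, 1), kern, 2)
  out <- num
  out[den > 0] <- num[den > 0] / den[den > 0]
  out[den == 0] <- NA_real_
  array(out, dim = dims)
}

phasor_histogram <- function(g, s, weight, n_bins) {
  ok <- is.finite(g) & is.finite(s) & g >= 0 & g <= 1 & s >= 0 & s <= 1
  h <- matrix(0, n_bins, n_bins)
  if (!any(ok)) return(h)
  gi <- pmin(floor(g[ok] * n_bins), n_bins - 1) + 1
  si <- pmin(floor(s[ok] * n_bins), n_bins - 1) + 1
  rs <- rowsum(weight[ok], group = (gi - 1) * n_bins + si, reorder = FALSE)
  h[as.integer(rownames(rs))] <- rs[, 1]
  h
}

# Segment-crossing test for polygon self-intersection (excluding shared
# endpoints of adjacent edges).
polygon_self_intersects <- function(poly) {
  k <- nrow(poly)
  seg <- cbind(poly, poly[c(2:k, 1), ])
  ccw <- function(ax, ay, bx, by, cx, cy) {
    (by - ay) * (cx - ax) - (bx - ax) * (cy - ay)
  }
  for (i in seq_len(k - 2)) {
    jmax <- if (i == 1) k - 1 else k
    for (j in (i + 2):jmax) {
      d1 <- ccw(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- ccw(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- ccw(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- ccw(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Back-project a phasor gate onto the image
#'
#' Selects the pixels whose smoothed phasor coordinates fall inside a
#' polygonal gate drawn in the `(g, s)` plane (boundary inclusive).
#'
#' @param map A [phasor_transform()] result.
#' @param gate `k x 2` matrix of polygon vertices `(g, s)`, `k >= 3`.
#' @return Logical mask with the pixel dimensions of the map.
#' @export
gate_backprojection <- function(map, gate) {
  gate <- as.matrix(gate)
  if (nrow(gate) < 3 || ncol(gate) != 2) stop("gate must be a k x 2 polygon")
  if (polygon_self_intersects(gate)) stop("self-intersecting gate polygon")
  g <- as.vector(map$g_smooth); s <- as.vector(map$s_smooth)
  inside <- rep(FALSE, length(g))
  ok <- is.finite(g) & is.finite(s)
  if (any(ok)) {
    inside[ok] <- pracma::inpolygon(g[ok], s[ok], gate[, 1], gate[, 2],
                                    boundary = TRUE)
  }
  array(inside, dim = dim(map$g))
}

#' Linked FRET efficiencies of the two donor conformers
#'
#' ECFP-type donors decay bi-exponentially (two conformers with lifetimes
#' `tau1`, `tau2`); when the donor FRETs, the two conformers' efficiencies
#' are linked through `E1/(1-E1) = (tau1/tau2) * E2/(1-E2)`.
#' `linked_efficiency()` maps the component-2 efficiency to component 1;
#' `linked_efficiency_inverse()` is the reverse map.
#'
#' @param E2,E1 FRET efficiency in `[0, 1)`.
#' @param tau1,tau2 Conformer lifetimes (same units).
#' @export
linked_efficiency <- function(E2, tau1, tau2) {
  if (any(E2 < 0 | E2 >= 1)) stop("efficiency must lie in [0, 1)")
  rho <- (tau1 / tau2) * E2 / (1 - E2)
  rho / (1 + rho)
}

#' @rdname linked_efficiency
#' @export
linked_efficiency_inverse <- function(E1, tau1, tau2) {
  if (any(E1 < 0 | E1 >= 1)) stop("efficiency must lie in [0, 1)")
  rho <- (tau2 / tau1) * E1 / (1 - E1)
  rho / (1 + rho)
}

#' Complex-donor decay for one biosensor conformation
#'
#' The donor decay when the biosensor is in a conformation with
#' component-1 FRET efficiency `E1`:
#' `F(t; E1) = sum_i beta_i exp(-t / (tau_i (1 - E_i)))`, the component-2
#' efficiency following from the linked relation. FRET shortens each
#' conformer lifetime to `tau_i (1 - E_i)`.
#'
#' @param t Times (same units as `tau`).
#' @param E1 Component-1 FRET efficiency in `[0, 1)`.
#' @param beta Fractional amplitudes of the two donor conformers
#'   (default `c(0.434, 0.566)`).
#' @param tau Conformer lifetimes (default `c(1330, 3350)` ps, in seconds).
#' @return `F(t)`; `F(0) = sum(beta)`.
#' @export
complex_donor_decay <- function(t, E1, beta = c(0.434, 0.566),
                                tau = c(1330e-12, 3350e-12)) {
  if (E1 < 0 || E1 >= 1) stop("E1 must lie in [0, 1)")
  E <- c(E1, linked_efficiency_inverse(E1, tau[1], tau[2]))
  taueff <- tau * (1 - E)
  if (any(taueff <= 0)) stop("effective lifetime vanished (E too close to 1)")
  beta[1] * exp(-t / taueff[1]) + beta[2] * exp(-t / taueff[2])
}

# IRF-convolved, binned version of complex_donor_decay (per-bin expected
# counts for unit amplitude).
fret_decay_curve <- function(t_centers, E1, beta, tau, irf_mu, irf_sigma,
                             rep_period) {
  E <- c(E1, linked_efficiency_inverse(E1, tau[1], tau[2]))
  taueff <- tau * (1 - E)
  decay_model_curve(t_centers, beta, taueff, irf_mu, irf_sigma, rep_period)
}

#' Global complex-donor FRET fraction fit
#'
#' Fits the two-conformation biosensor model
#' `I(t) = I * (gammaH * F(t; E1H) + (1 - gammaH) * F(t; E1L))` to a FLIM
#' image: the high- and low-activity efficiencies `(E1H, E1L)` are shared
#' globally across all masked pixels (Poisson maximum likelihood), while
#' each pixel's amplitudes are profiled out by a non-negative linear
#' solve, giving the per-pixel active fraction
#' `gammaH = aH / (aH + aL)`. Donor lifetimes, fractions and the Gaussian
#' IRF are fixed inputs.
#'
#' @param x A `flim_image` (single channel) or an array `[n_y, n_x, n_t]`
#'   / matrix `[n_pixels, n_t]` of decay histograms.
#' @param tau Donor conformer lifetimes in seconds
#'   (default `c(1330, 3350)` ps).
#' @param beta1 Fractional contribution of the first conformer
#'   (default 0.434).
#' @param irf_mu,irf_sigma Gaussian IRF parameters in seconds.
#' @param rep_period Repetition period in seconds (defaults to the
#'   geometry carried by a `flim_image`).
#' @param min_photons Pixels with fewer total counts are excluded
#'   (default 100).
#' @param start Starting values for `c(E1H, E1L)`.
#' @param fix_efficiencies Optional `c(E1H, E1L)`: skip the global
#'   optimisation and only solve the per-pixel fractions (used when the
#'   conformation efficiencies are already known; also the only
#'   identifiable setting when a single conformation dominates the image).
#' @return Object of class `fret_fit`: `E1H`, `E1L`, `gammaH` (per pixel,
#'   in `[0, 1]`), `gammaH_unconstrained` (pre-clamp, from the
#'   unconstrained linear solve), `amplitude`, `mask`, `nll`, `converged`.
#' @export
fit_fret_fraction <- function(x, tau = c(1330e-12, 3350e-12), beta1 = 0.434,
                              irf_mu = 1e-9, irf_sigma = 100e-12,
                              rep_period = NULL, min_photons = 100,
                              start = c(0.5, 0.05),
                              fix_efficiencies = NULL) {
  beta <- c(beta1, 1 - beta1)
  Yd <- decay_matrix(x, rep_period)
  Y <- Yd$Y; rep_period <- Yd$rep_period; pix_dims <- Yd$pix_dims
  nt <- ncol(Y)
  tc <- (seq_len(nt) - 0.5) * rep_period / nt
  tot <- rowSums(Y)
  mask <- tot >= min_photons
  if (!any(mask)) stop("insufficient data: no pixel reaches min_photons")
  Ym <- Y[mask, , drop = FALSE]

  curves <- function(E) {
    cbind(fret_decay_curve(tc, E[1], beta, tau, irf_mu, irf_sigma, rep_period),
          fret_decay_curve(tc, E[2], beta, tau, irf_mu, irf_sigma, rep_period))
  }
  # profile the per-pixel non-negative amplitudes (aH, aL) analytically
  profile_amp <- function(FF, Y) {
    SHH <- sum(FF[, 1]^2); SLL <- sum(FF[, 2]^2); SHL <- sum(FF[, 1] * FF[, 2])
    bH <- as.numeric(Y %*% FF[, 1]); bL <- as.numeric(Y %*% FF[, 2])
    det <- SHH * SLL - SHL^2
    if (det <= 1e-12 * SHH * SLL) {    # near-identical curves
      a <- pmax(bH / SHH, 0)
      return(list(a = a, b = a * 0, raw = cbind(a, a * 0)))
    }
    a <- (SLL * bH - SHL * bL) / det
    b <- (SHH * bL - SHL * bH) / det
    raw <- cbind(a, b)
    neg_a <- a < 0; neg_b <- b < 0
    a[neg_a] <- 0; b[neg_a] <- pmax(bL[neg_a] / SLL, 0)
    b[neg_b & !neg_a] <- 0
    a[neg_b & !neg_a] <- pmax(bH[neg_b & !neg_a] / SHH, 0)
    list(a = a, b = b, raw = raw)
  }
  nll <- function(par) {
    E <- stats::plogis(par)
    FF <- curves(E)
    amp <- profile_amp(FF, Ym)
    M <- amp$a %o% FF[, 1] + amp$b %o% FF[, 2]
    M <- pmax(M, 1e-12)
    sum(M - Ym * log(M))
  }
  if (is.null(fix_efficiencies)) {
    opt <- stats::optim(stats::qlogis(start), nll, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-8))
    E <- stats::plogis(opt$par)
    conv <- opt$convergence == 0
    val <- opt$value
  } else {
    E <- fix_efficiencies
    conv <- TRUE
    val <- nll(stats::qlogis(E))
  }
  if (E[1] < E[2]) E <- rev(E)          # E1H is the high-activity efficiency
  FF <- curves(E)
  amp <- profile_amp(FF, Y)
  gam <- rep(NA_real_, nrow(Y))
  den <- amp$a + amp$b
  gam[den > 0] <- amp$a[den > 0] / den[den > 0]
  gam_raw <- rep(NA_real_, nrow(Y))
  den_raw <- amp$raw[, 1] + amp$raw[, 2]
  gam_raw[den_raw != 0] <- amp$raw[den_raw != 0, 1] / den_raw[den_raw != 0]
  gam[!mask] <- NA_real_; gam_raw[!mask] <- NA_real_
  shape <- function(v) if (length(pix_dims) > 1) array(v, pix_dims) else v
  structure(list(E1H = E[1], E1L = E[2],
                 gammaH = shape(pmin(pmax(gam, 0), 1)),
                 gammaH_unconstrained = shape(gam_raw),
                 amplitude = shape(den), mask = shape(mask),
                 nll = val, converged = conv),
            class = "fret_fit")
}

#' @export
print.fret_fit <- function(x, ...) {
  cat(sprintf("fret_fit: E1H = %.3f, E1L = %.3f, mean gammaH = %.3f (%d px)%s\n",
              x$E1H, x$E1L, mean(x$gammaH, na.rm = TRUE), sum(x$mask),
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

# Normalise decay inputs to a pixels x time matrix.
decay_matrix <- function(x, rep_period) {
  if (inherits(x, "flim_image")) {
    if (is.null(rep_period)) rep_period <- x$geometry$rep_period
    h <- x$histogram
    d <- dim(h)
    if (d[4] > 1) stop("expected single-channel FLIM data")
    Y <- matrix(h, ncol = d[5])
    pix_dims <- d[1:3]
    if (d[3] == 1) pix_dims <- d[1:2]
  } else {
    if (is.null(rep_period)) stop("rep_period must be supplied")
    dims <- dim(x)
    if (is.null(dims)) {
      Y <- matrix(x, nrow = 1); pix_dims <- 1L
    } else {
      Y <- matrix(x, ncol = dims[length(dims)])
      pix_dims <- dims[-length(dims)]
    }
  }
  list(Y = Y, rep_period = rep_period, pix_dims = pix_dims)
}

#' Single-exponential lifetime fit of a decay histogram
#'
#' Poisson maximum-likelihood estimate of the lifetime from a micro-time
#' histogram, with the model exponential convolved with a Gaussian IRF and
#' wrapped at the repetition period. The histogram is treated as spanning
#' one repetition period.
#'
#' @param decay Numeric vector of counts per micro-time bin.
#' @param irf_mu,irf_sigma Gaussian IRF parameters in seconds.
#' @param rep_period Repetition period in seconds.
#' @param min_photons Minimum total counts (default 50).
#' @param tau_range Search interval in seconds.
#' @return list: `tau` (seconds), `amplitude` (total counts), `converged`.
#' @export
fit_single_exponential <- function(decay, irf_mu = 1e-9, irf_sigma = 100e-12,
                                   rep_period = 12.5e-9, min_photons = 50,
                                   tau_range = c(20e-12, 30e-9)) {
  tot <- sum(decay)
  if (tot < min_photons) {
    stop(sprintf("insufficient photons: %d < %d", round(tot), min_photons))
  }
  nt <- length(decay)
  tc <- (seq_len(nt) - 0.5) * rep_period / nt
  negll <- function(log_tau) {
    p <- emg_density(tc, exp(log_tau), irf_mu, irf_sigma, rep_period)
    p <- pmax(p / sum(p), 1e-300)
    -sum(decay * log(p))
  }
  opt <- stats::optimize(negll, log(tau_range), tol = 1e-10)
  tau <- exp(opt$minimum)
  edge <- min(abs(log(tau) - log(tau_range))) < 1e-3
  list(tau = tau, amplitude = tot, converged = !edge)
}

#' Per-pixel lifetime image
#'
#' Applies [fit_single_exponential()] to every pixel of a FLIM image,
#' optionally after a `3 x 3` box binning of neighbouring decays to raise
#' the per-fit photon count. Pixels below the photon threshold or at a
#' search-boundary fit are returned as NA.
#'
#' @inheritParams fit_single_exponential
#' @param x A `flim_image` or `[n_y, n_x, n_t]` array.
#' @param binning Odd box width for spatial pre-binning (default 3; 1
#'   disables).
#' @return list: `tau` (matrix, seconds), `intensity` (matrix, counts).
#' @export
fit_lifetime_image <- function(x, irf_mu = 1e-9, irf_sigma = 100e-12,
                               rep_period = NULL, min_photons = 50,
                               binning = 3L) {
  Yd <- decay_matrix(x, rep_period)
  pix <- Yd$pix_dims
  if (length(pix) < 2) stop("expected image-shaped FLIM data")
  nt <- ncol(Yd$Y)
  arr <- array(Yd$Y, dim = c(pix[1], pix[2], nt))
  if (binning > 1) {
    k <- rep(1, binning)                      # box sum, not mean
    arr <- convolve_dim(convolve_dim(arr, k, 1), k, 2)
  }
  tau <- matrix(NA_real_, pix[1], pix[2])
  inten <- apply(arr, c(1, 2), sum)
  for (i in seq_len(pix[1])) {
    for (j in seq_len(pix[2])) {
      if (inten[i, j] < min_photons) next
      ft <- fit_single_exponential(arr[i, j, ], irf_mu, irf_sigma,
                                   Yd$rep_period, min_photons)
      tau[i, j] <- if (ft$converged) ft$tau else NA_real_
    }
  }
  list(tau = tau, intensity = inten)
}

#' Fit a multispectral decay pattern
#'
#' Builds the reference "pattern" used for spectral unmixing: for each
#' spectral channel, the summed decay of a region is fitted to a
#' 4-component exponential model convolved with the IRF (non-negative
#' amplitudes profiled by NNLS, lifetimes optimised), and the full
#' time-by-channel pattern is normalised to unit total sum.
#'
#' @param summed_decays `n_t x n_channels` matrix of summed counts.
#' @param irf_mu,irf_sigma Gaussian IRF parameters in seconds.
#' @param rep_period Repetition period in seconds.
#' @param n_components Exponential components per channel (default 4).
#' @param tau_init Initial lifetimes in seconds.
#' @return Object of class `spectral_pattern`: `curves` (normalised
#'   `n_t x n_channels`), `amplitudes`, `lifetimes` (per channel).
#' @export
generate_pattern <- function(summed_decays, irf_mu = 1e-9,
                             irf_sigma = 100e-12, rep_period = 12.5e-9,
                             n_components = 4L,
                             tau_init = c(0.3e-9, 1e-9, 2.5e-9, 5e-9)) {
  summed_decays <- as.matrix(summed_decays)
  nt <- nrow(summed_decays); nch <- ncol(summed_decays)
  if (nt < 2 * n_components) {
    stop("fewer time bins than model parameters")
  }
  tau_init <- tau_init[seq_len(n_components)]
  tc <- (seq_len(nt) - 0.5) * rep_period / nt
  basis <- function(log_tau) {
    vapply(exp(log_tau), function(tau) {
      tau * emg_density(tc, tau, irf_mu, irf_sigma, rep_period)
    }, numeric(nt))
  }
  curves <- matrix(0, nt, nch)
  amps <- matrix(0, n_components, nch)
  taus <- matrix(NA_real_, n_components, nch)
  for (ch in seq_len(nch)) {
    y <- summed_decays[, ch]
    if (sum(y) == 0) next                       # zero channel -> zero pattern
    rss <- function(log_tau) {
      B <- basis(log_tau)
      a <- pracma::lsqnonneg(B, y)$x
      sum((B %*% a - y)^2)
    }
    opt <- stats::optim(log(tau_init), rss, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    B <- basis(opt$par)
    a <- pracma::lsqnonneg(B, y)$x
    curves[, ch] <- B %*% a
    amps[, ch] <- a
    taus[, ch] <- exp(opt$par)
  }
  tot <- sum(curves)
  if (tot > 0) curves <- curves / tot
  structure(list(curves = curves, amplitudes = amps, lifetimes = taus),
            class = "spectral_pattern")
}

#' Non-negative least-squares spectral unmixing
#'
#' Solves `min || P gamma - y ||^2` subject to `gamma >= 0`, where each
#' column of `P` is a reference pattern stacked over time bins and
#' spectral channels and `y` is one pixel's stacked decay.
#'
#' @param pixel_decays `n_t x n_channels` matrix (or already-stacked
#'   vector) for one pixel.
#' @param patterns List of [generate_pattern()] results (or numeric
#'   matrices/vectors of matching length).
#' @return Non-negative abundance vector, one entry per pattern.
#' @export
nnls_unmix <- function(pixel_decays, patterns) {
  y <- as.numeric(pixel_decays)
  cols <- lapply(patterns, function(p) {
    if (inherits(p, "spectral_pattern")) as.numeric(p$curves) else as.numeric(p)
  })
  P <- do.call(cbind, cols)
  if (nrow(P) != length(y)) stop("pattern and pixel stacks differ in length")
  if (qr(P)$rank < ncol(P)) {
    warning("rank-deficient pattern matrix; abundances are not unique")
  }
  pracma::lsqnonneg(P, y)$x
}
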
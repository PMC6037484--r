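# Analytic wrapped mono-exponential decay sampled at bin centres: under
# periodic re-excitation the phasor of this decay sits exactly on the
# universal semicircle.
wrapped_exponential <- function(tau, T, nt) {
  tc <- (seq_len(nt) - 0.5) * T / nt
  exp(-tc / tau) / (1 - exp(-T / tau))
}

test_that("phasor coordinates obey the closed forms", {
  T <- 12.5e-9
  w <- 2 * pi / T
  nt <- 2^18

  # near-delta decay at t = 0 maps to (1, 0)
  delta <- c(1, rep(0, nt - 1))
  pm <- phasor_transform(array(delta, dim = c(1, 1, nt)), T)
  expect_equal(as.numeric(pm$g), 1, tolerance = 1e-4)
  expect_equal(as.numeric(pm$s), 0, tolerance = 1e-4)

  # mono-exponential: g = 1/(1 + (w tau)^2), s = w tau g, on the semicircle
  for (tau in c(0.5e-9, 2e-9, 4e-9)) {
    pm <- phasor_transform(array(wrapped_exponential(tau, T, nt),
                                 dim = c(1, 1, nt)), T)
    g <- as.numeric(pm$g); s <- as.numeric(pm$s)
    expect_equal(g, 1 / (1 + (w * tau)^2), tolerance = 1e-9)
    expect_equal(s, w * tau / (1 + (w * tau)^2), tolerance = 1e-9)
    expect_equal((g - 0.5)^2 + s^2, 0.25, tolerance = 1e-9)
  }

  # wtau = 1 sits at (0.5, 0.5)
  pm1 <- phasor_transform(array(wrapped_exponential(1 / w, T, nt),
                                dim = c(1, 1, nt)), T)
  expect_equal(as.numeric(pm1$g), 0.5, tolerance = 1e-9)
  expect_equal(as.numeric(pm1$s), 0.5, tolerance = 1e-9)
})

test_that("the phasor transform is linear in intensity", {
  T <- 12.5e-9; nt <- 512
  d1 <- wrapped_exponential(1e-9, T, nt)
  d2 <- wrapped_exponential(3.5e-9, T, nt)
  w1 <- 3; w2 <- 1                            # 3:1 intensity mixture
  mix <- w1 * d1 + w2 * d2
  stack <- array(0, dim = c(3, 1, nt))
  stack[1, 1, ] <- d1; stack[2, 1, ] <- d2; stack[3, 1, ] <- mix
  pm <- phasor_transform(stack, T)
  i1 <- sum(d1) * w1; i2 <- sum(d2) * w2
  expect_equal(pm$g[3, 1], (i1 * pm$g[1, 1] + i2 * pm$g[2, 1]) / (i1 + i2),
               tolerance = 1e-12)
  expect_equal(pm$s[3, 1], (i1 * pm$s[1, 1] + i2 * pm$s[2, 1]) / (i1 + i2),
               tolerance = 1e-12)
  # zero-intensity pixels are masked
  stack[2, 1, ] <- 0
  pm0 <- phasor_transform(stack, T)
  expect_true(is.na(pm0$g[2, 1]))
})

test_that("phasor gates select the intended population", {
  set.seed(80)
  T <- 12.5e-9; nt <- 64
  n <- 32
  # two spatially separated populations with a dark gap between them,
  # so 5x5 smoothing cannot blend their phasor clusters
  tau_map <- matrix(NA_real_, n, n)
  tau_map[, 1:12] <- 0.8e-9
  tau_map[, 21:32] <- 3.2e-9
  counts <- array(0, dim = c(n, n, nt))
  tc <- (seq_len(nt) - 0.5) * T / nt
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (is.na(tau_map[i, j])) next
    lam <- 2e4 * exp(-tc / tau_map[i, j]) / sum(exp(-tc / tau_map[i, j]))
    counts[i, j, ] <- rpois(nt, lam)
  }
  pm <- phasor_transform(counts, T)

  # gate around the short-lifetime cluster
  w <- 2 * pi / T
  g0 <- 1 / (1 + (w * 0.8e-9)^2); s0 <- w * 0.8e-9 * g0
  gate <- cbind(g0 + c(-0.12, 0.12, 0.12, -0.12),
                s0 + c(-0.12, -0.12, 0.12, 0.12))
  sel <- gate_backprojection(pm, gate)
  truth <- !is.na(tau_map) & tau_map < 1e-9
  valid <- !is.na(pm$g)
  expect_gt(mean(sel[valid] == truth[valid]), 0.99)

  # whole unit square selects every valid pixel; a far-away gate none
  all_gate <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_true(all(gate_backprojection(pm, all_gate)[valid]))
  far <- cbind(c(0.96, 0.99, 0.99, 0.96), c(0.9, 0.9, 0.99, 0.99))
  expect_false(any(gate_backprojection(pm, far)))

  bowtie <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(gate_backprojection(pm, bowtie), "self-intersecting")
})

test_that("linked conformer efficiencies follow the lifetime-ratio relation", {
  tau1 <- 1330e-12; tau2 <- 3350e-12
  expect_equal(linked_efficiency(0, tau1, tau2), 0)
  expect_equal(linked_efficiency(0.37, 2e-9, 2e-9), 0.37)

  # independent oracle: root-solve the defining relation for E1
  for (E2 in c(0.1, 0.5, 0.9)) {
    root <- uniroot(function(E1) {
      E1 / (1 - E1) - (tau1 / tau2) * E2 / (1 - E2)
    }, c(0, 1 - 1e-12), tol = 1e-14)$root
    expect_equal(linked_efficiency(E2, tau1, tau2), root, tolerance = 1e-9)
  }
  # round trip: inverse after forward is the identity on [0, 1)
  E2s <- seq(0, 0.95, by = 0.05)
  expect_equal(linked_efficiency_inverse(
    linked_efficiency(E2s, tau1, tau2), tau1, tau2), E2s, tolerance = 1e-12)
  expect_error(linked_efficiency(1, tau1, tau2), "\\[0, 1\\)")
})

test_that("the complex-donor decay has the stated amplitude and area", {
  tau <- c(1330e-12, 3350e-12)
  beta <- c(0.434, 0.566)
  ts <- seq(0, 30e-9, length.out = 500)
  expect_equal(complex_donor_decay(ts, 0, beta, tau),
               beta[1] * exp(-ts / tau[1]) + beta[2] * exp(-ts / tau[2]))
  expect_equal(complex_donor_decay(0, 0.4, beta, tau), sum(beta))

  for (E1 in c(0, 0.3, 0.65)) {
    E2 <- linked_efficiency_inverse(E1, tau[1], tau[2])
    want <- beta[1] * tau[1] * (1 - E1) + beta[2] * tau[2] * (1 - E2)
    got <- integrate(function(t) complex_donor_decay(t, E1, beta, tau),
                     0, Inf, rel.tol = 1e-10)$value
    expect_equal(got, want, tolerance = 1e-6)
  }
  expect_error(complex_donor_decay(ts, 1.2), "\\[0, 1\\)")
})

test_that("single-exponential lifetimes are recovered without bias", {
  T <- 12.5e-9; nt <- 256
  tc <- (seq_len(nt) - 0.5) * T / nt

  # noiseless self-consistency at tau = 2 ns
  curve <- flimreg:::emg_density(tc, 2e-9, 1e-9, 100e-12, T)
  fit <- fit_single_exponential(1e6 * curve / sum(curve), rep_period = T)
  expect_equal(fit$tau, 2e-9, tolerance = 1e-3)

  # Monte-Carlo at 1000 photons: bias < 1%, spread consistent with the
  # Cramer-Rao bound within a factor 1.5
  set.seed(81)
  p <- curve / sum(curve)
  taus <- replicate(200, {
    y <- rpois(nt, 1000 * p)
    fit_single_exponential(y, rep_period = T)$tau
  })
  expect_lt(abs(mean(taus) - 2e-9) / 2e-9, 0.01)
  h <- 1e-13
  pp <- flimreg:::emg_density(tc, 2e-9 + h, 1e-9, 100e-12, T)
  pm <- flimreg:::emg_density(tc, 2e-9 - h, 1e-9, 100e-12, T)
  dlogp <- (log(pp / sum(pp)) - log(pm / sum(pm))) / (2 * h)
  crb <- 1 / sqrt(1000 * sum(p * dlogp^2))
  expect_lt(sd(taus) / crb, 1.5)
  expect_gt(sd(taus) / crb, 1 / 1.5)

  # incomplete decay: tau close to the repetition period still converges
  curve2 <- flimreg:::emg_density(tc, 10e-9, 1e-9, 100e-12, T)
  set.seed(82)
  y2 <- rpois(nt, 5e4 * curve2 / sum(curve2))
  fit2 <- fit_single_exponential(y2, rep_period = T)
  expect_true(fit2$converged)
  expect_lt(abs(fit2$tau - 10e-9) / 10e-9, 0.15)

  expect_error(fit_single_exponential(c(3, 2, 1), rep_period = T),
               "insufficient photons")
})

test_that("per-pixel lifetime images honour binning and thresholds", {
  T <- 12.5e-9; nt <- 64
  tc <- (seq_len(nt) - 0.5) * T / nt
  set.seed(83)
  arr <- array(0, dim = c(6, 6, nt))
  p <- flimreg:::emg_density(tc, 1.5e-9, 1e-9, 100e-12, T)
  p <- p / sum(p)
  for (i in 1:6) for (j in 1:6) arr[i, j, ] <- rpois(nt, 200 * p)
  arr[1, 1, ] <- 0                            # empty pixel stays NA
  res <- fit_lifetime_image(arr, rep_period = T, binning = 3L)
  expect_true(is.na(res$tau[1, 1]) || res$tau[1, 1] > 0)  # binning may fill it
  inner <- res$tau[2:5, 2:5]
  expect_lt(max(abs(inner - 1.5e-9) / 1.5e-9), 0.1)
})

test_that("the global FRET fraction fit recovers the active-fraction map", {
  set.seed(84)
  T <- 12.5e-9; nt <- 64
  tc <- (seq_len(nt) - 0.5) * T / nt
  tau <- c(1330e-12, 3350e-12); beta <- c(0.434, 0.566)
  E1H <- 0.65; E1L <- 0.02
  n <- 22
  gam_true <- matrix(rep(seq(0, 1, length.out = n), each = n), n, n)
  FH <- flimreg:::fret_decay_curve(tc, E1H, beta, tau, 1e-9, 100e-12, T)
  FL <- flimreg:::fret_decay_curve(tc, E1L, beta, tau, 1e-9, 100e-12, T)
  photons <- 500
  Y <- array(0, dim = c(n, n, nt))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shape <- gam_true[i, j] * FH + (1 - gam_true[i, j]) * FL
    Y[i, j, ] <- rpois(nt, photons * shape / sum(shape))
  }
  fit <- fit_fret_fraction(Y, tau = tau, beta1 = beta[1], rep_period = T,
                           min_photons = 100)
  expect_equal(fit$E1H, E1H, tolerance = 0.1)
  expect_lt(fit$E1L, 0.15)
  rmse <- sqrt(mean((fit$gammaH - gam_true)^2, na.rm = TRUE))
  expect_lt(rmse, 0.1)

  # degenerate mixtures at the ends of the range: with one conformation
  # absent the second efficiency is unidentifiable, so the globals are
  # held at their known values and only the fractions are solved
  for (g0 in c(0, 1)) {
    Y0 <- array(0, dim = c(8, 8, nt))
    shape <- g0 * FH + (1 - g0) * FL
    for (i in 1:8) for (j in 1:8) {
      Y0[i, j, ] <- rpois(nt, 3000 * shape / sum(shape))
    }
    f0 <- fit_fret_fraction(Y0, tau = tau, beta1 = beta[1], rep_period = T,
                            fix_efficiencies = c(E1H, E1L))
    if (g0 == 0) expect_lt(mean(f0$gammaH, na.rm = TRUE), 0.05)
    if (g0 == 1) expect_gt(mean(f0$gammaH, na.rm = TRUE), 0.95)
  }
})

test_that("spectral patterns reproduce simpler decays and normalise", {
  set.seed(85)
  T <- 12.5e-9; nt <- 128
  tc <- (seq_len(nt) - 0.5) * T / nt
  truth <- 4e5 * (0.6 * flimreg:::emg_density(tc, 0.9e-9, 1e-9, 100e-12, T) +
                  0.4 * flimreg:::emg_density(tc, 3.1e-9, 1e-9, 100e-12, T))
  truth <- truth / sum(truth) * 4e5
  y <- rpois(nt, truth)
  pat <- generate_pattern(cbind(y), rep_period = T)
  fitted <- pat$curves[, 1] / sum(pat$curves[, 1]) * sum(y)
  chi2 <- sum((y - fitted)^2 / pmax(fitted, 1)) / (nt - 8)
  expect_gt(chi2, 0.6)
  expect_lt(chi2, 1.5)
  expect_equal(sum(pat$curves), 1)

  # scale invariance of the normalised pattern
  pat2 <- generate_pattern(cbind(5 * y), rep_period = T)
  expect_equal(pat2$curves, pat$curves, tolerance = 1e-8)

  # a zero channel yields a zero pattern column
  pat3 <- generate_pattern(cbind(y, 0), rep_period = T)
  expect_true(all(pat3$curves[, 2] == 0))
  expect_error(generate_pattern(cbind(y[1:6]), rep_period = T),
               "fewer time bins")
})

test_that("NNLS unmixing matches the exhaustive active-set oracle", {
  set.seed(86)
  nt <- 40
  P <- cbind(exp(-(1:nt) / 4), exp(-(1:nt) / 12), exp(-((1:nt) - 8)^2 / 30))
  P <- sweep(P, 2, colSums(P), "/")
  pats <- lapply(1:3, function(j) P[, j])

  expect_equal(nnls_unmix(2 * P[, 1], pats), c(2, 0, 0), tolerance = 1e-10)
  expect_equal(nnls_unmix(1 * P[, 1] + 3 * P[, 2], pats), c(1, 3, 0),
               tolerance = 1e-8)
  expect_equal(nnls_unmix(-P[, 1], pats), c(0, 0, 0), tolerance = 1e-10)

  # oracle: enumerate all active sets, solve the reduced LS, keep the best
  # feasible solution
  nnls_oracle <- function(y) {
    best <- NULL; best_rss <- Inf
    for (mask in 0:7) {
      on <- which(bitwAnd(mask, c(1, 2, 4)) > 0)
      x <- rep(0, 3)
      if (length(on)) {
        sol <- qr.solve(P[, on, drop = FALSE], y)
        if (any(sol < -1e-12)) next
        x[on] <- pmax(sol, 0)
      }
      rss <- sum((y - P %*% x)^2)
      if (rss < best_rss - 1e-15) { best_rss <- rss; best <- x }
    }
    best
  }
  for (rep in 1:20) {
    y <- P %*% pmax(rnorm(3, 1, 1.5), -0.5) + rnorm(nt, 0, 0.002)
    expect_equal(nnls_unmix(y, pats), nnls_oracle(as.numeric(y)),
                 tolerance = 1e-8)
  }

  # NNLS equals unconstrained LS whenever the latter is non-negative
  y2 <- P %*% c(1, 2, 0.5)
  expect_equal(nnls_unmix(y2, pats),
               as.numeric(qr.solve(P, y2)), tolerance = 1e-8)

  expect_warning(nnls_unmix(P[, 1], list(P[, 1], P[, 1])), "rank-deficient")
})
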
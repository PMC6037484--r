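test_that("the precomputed Hessian matches dense accumulation and is banded", {
  for (cfg in list(list(tmpl = smooth_scene(24, seed = 1),
                        geom = tiny_geometry(24L, 24L), d = 2L),
                   list(tmpl = smooth_scene_3d(12, 4, seed = 2),
                        geom = geometry_3d(12L, 12L, 4L), d = 3L))) {
    n <- 5L
    model <- precompute_reference(cfg$tmpl, n, cfg$geom, sigma_x = 1)
    expect_identical(model$d, cfg$d)

    # dense oracle: accumulate outer products voxel by voxel
    J <- as.matrix(displacement_jacobian(cfg$geom, n, cfg$d))
    gv <- do.call(cbind, lapply(model$gradients, as.vector))
    m <- n * cfg$d
    H <- matrix(0, m, m)
    for (v in seq_len(nrow(gv))) {
      a <- gv[v, ] %*% J[((v - 1) * cfg$d + 1):(v * cfg$d), , drop = FALSE]
      H <- H + crossprod(a)
    }
    expect_lt(max(abs(H - model$H)), 1e-8)

    # exact symmetry and adjacent-knot support
    expect_identical(max(abs(model$H - t(model$H))), 0)
    far <- model$H[seq_len(cfg$d), (2 * cfg$d + 1):(3 * cfg$d)]
    expect_identical(max(abs(far)), 0)

    # bandwidth: 2d diagonals at or above the main diagonal
    expect_identical(flimreg:::count_nonzero_upper_diagonals(model$H),
                     as.integer(2 * cfg$d))
  }
  expect_error(precompute_reference(array(1, c(8, 8, 1)), 3, tiny_geometry(8L, 8L)),
               "degenerate template")
})

test_that("error and gradient vanish at perfect alignment and scale quadratically", {
  geom <- tiny_geometry(24L, 24L)
  tmpl <- smooth_scene(24, seed = 3)
  model <- precompute_reference(tmpl, 4, geom, sigma_x = 2)
  tmpl_s <- smooth_fast_axis(tmpl, 2) / model$norm
  eg <- error_and_gradient(model, tmpl_s, rep(0, 8))
  expect_equal(eg$E, 0)
  expect_equal(eg$g, rep(0, 8))

  # doubling the residual quadruples the error
  set.seed(6)
  frame <- tmpl_s * (1 + 0.1 * array(runif(length(tmpl_s)), dim(tmpl_s)))
  e1 <- error_and_gradient(model, frame, rep(0, 8))$E
  e2 <- error_and_gradient(model, 2 * frame - model$template, rep(0, 8))$E
  expect_equal(e2, 4 * e1, tolerance = 1e-12)
})

test_that("the inverse-compositional gradient matches finite differences", {
  geom <- tiny_geometry(32L, 32L)
  tmpl <- smooth_scene(32, seed = 4)
  model <- precompute_reference(tmpl, 4, geom, sigma_x = 2)
  set.seed(9)
  p <- rnorm(8, sd = 0.5)
  frame_s <- warp_stack(smooth_fast_axis(tmpl, 2) / model$norm,
                        trace_from_parameters(rnorm(8, sd = 0.3), 4, 2,
                                              geom$t_frame), geom)$intensity
  # interior voxels: one pixel clear of every border so the template warp
  # stays valid under the probe displacements and no mask terms enter
  interior <- array(FALSE, dim = dim(tmpl))
  interior[2:31, 2:31, 1] <- TRUE
  wf <- warp_stack(frame_s, trace_from_parameters(p, 4, 2, geom$t_frame), geom)
  mask <- wf$valid_mask & interior
  res <- (wf$intensity - model$template) * mask
  g <- 2 * as.numeric(Matrix::crossprod(model$A, as.vector(res)))

  # oracle: central differences over the template-side update of the IC
  # objective E'(dp) = sum((warped frame at p) - (warped template at dp))^2;
  # d/ddp at dp = 0 equals -g
  E_ic <- function(dp) {
    wt <- warp_stack(model$template,
                     trace_from_parameters(dp, 4, 2, geom$t_frame), geom)
    sum(((wf$intensity - wt$intensity)[mask])^2)
  }
  h <- 1e-5
  fd <- vapply(1:8, function(j) {
    dp <- rep(0, 8); dm <- rep(0, 8)
    dp[j] <- h; dm[j] <- -h
    (E_ic(dp) - E_ic(dm)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(fd + g)) / max(abs(g)), 1e-3)
})

test_that("forward-error finite differences agree with the IC gradient near alignment", {
  geom <- tiny_geometry(32L, 32L)
  tmpl <- smooth_scene(32, seed = 12)
  model <- precompute_reference(tmpl, 3, geom, sigma_x = 2)
  tmpl_s <- smooth_fast_axis(tmpl, 2) / model$norm
  set.seed(2)
  p <- rnorm(6, sd = 0.05)
  eg <- error_and_gradient(model, tmpl_s, p)
  h <- 1e-5
  fd <- vapply(1:6, function(j) {
    pp <- p; pm <- p
    pp[j] <- p[j] + h; pm[j] <- p[j] - h
    (error_and_gradient(model, tmpl_s, pp)$E -
       error_and_gradient(model, tmpl_s, pm)$E) / (2 * h)
  }, numeric(1))
  # first-order IC approximation: agreement degrades linearly in |p|
  expect_lt(max(abs(fd - eg$g)) / max(abs(fd)), 0.05)
})

test_that("trust-region steps solve the banded subproblem", {
  set.seed(14)
  m <- 12L; kd <- 3L
  for (rep in 1:5) {
    B <- crossprod(matrix(rnorm(m * m), m)) + diag(m) * (2 + rep)
    B[abs(row(B) - col(B)) > kd] <- 0
    g <- rnorm(m)
    ab <- flimreg:::band_from_dense(B, kd)

    expect_equal(trust_region_step(ab, rep(0, m), 1), rep(0, m))

    # large radius: exact Newton step, checked against dense linear algebra
    s <- trust_region_step(ab, g, delta = 1e4)
    expect_lt(max(abs(s - solve(2 * B, -g))), 1e-8)

    # tiny radius: boundary solution with ||s|| = delta
    s2 <- trust_region_step(ab, g, delta = 1e-3)
    expect_equal(sqrt(sum(s2^2)), 1e-3, tolerance = 1e-4)
    # boundary step still reduces the model more than the scaled gradient
    q <- function(s) sum(g * s) + sum(s * (B %*% s))
    expect_lte(q(s2), q(-1e-3 * g / sqrt(sum(g^2))) + 1e-12)
  }
  expect_error(trust_region_step(diag(2), c(1, 1), 0), "positive")
})

test_that("banded Cholesky agrees with dense factorisation", {
  set.seed(15)
  for (m in c(6L, 20L, 45L)) {
    kd <- 5L
    A <- crossprod(matrix(rnorm(m * m), m)) + diag(m) * m
    A[abs(row(A) - col(A)) > kd] <- 0
    ab <- flimreg:::band_from_dense(A, kd)
    L <- flimreg:::band_chol(ab)
    b <- rnorm(m)
    expect_lt(max(abs(flimreg:::band_chol_solve(L, b) - solve(A, b))), 1e-8)
    expect_lt(max(abs(flimreg:::band_to_dense(ab) - A)), 1e-12)
  }
  # non-positive-definite input is reported
  bad <- flimreg:::band_from_dense(diag(c(1, -1, 1)), 1L)
  expect_error(flimreg:::band_chol(bad), "non-positive pivot")
})

test_that("fitting a frame against itself returns a null trace", {
  geom <- tiny_geometry(32L, 32L)
  tmpl <- array(make_test_image(32, 32, seed = 20), dim = c(32, 32, 1))
  model <- precompute_reference(tmpl, 4, geom, sigma_x = 2)
  fit <- estimate_frame_motion(model, tmpl)
  expect_lt(max(abs(fit$trace$knots)), 0.05)
  expect_gt(fit$r, 0.999)
  expect_true(fit$converged)
})

test_that("known smooth warps are recovered with reduced error", {
  geom <- tiny_geometry(48L, 48L)
  tmpl <- array(make_test_image(48, 48, seed = 21), dim = c(48, 48, 1))
  model <- precompute_reference(tmpl, 4, geom, sigma_x = 2)
  set.seed(22)
  for (rep in 1:3) {
    kn <- matrix(rnorm(8, sd = 1.2), 4, 2)
    frame <- warp_stack(tmpl, displacement_trace(kn, geom$t_frame),
                        geom)$intensity
    fit <- estimate_frame_motion(model, frame)
    frame_s <- smooth_fast_axis(frame, 2) / model$norm
    E0 <- error_and_gradient(model, frame_s, rep(0, 8))$E
    expect_lt(fit$E, E0)                     # progress over the null start
    # the estimated trace undoes the generating warp (opposite sign);
    # scored over pixel times, which weights the endpoint knots by their
    # actual support
    tpx <- as.vector(flimreg:::pixel_time_array(geom))[seq(1, 48 * 48, 5)]
    err <- displacement_at(fit$trace, tpx) +
      displacement_at(displacement_trace(kn, geom$t_frame), tpx)
    expect_lt(sqrt(mean(err^2)), 0.5)
    # r is scored over the full image: the synthetic frame's own zero
    # strips (cut by the generating warp) cap it below the noise-free limit
    expect_gt(fit$r, 0.9)
  }
})

test_that("frame correlation reproduces the Pearson formula", {
  set.seed(23)
  a <- array(runif(64), dim = c(8, 8, 1))
  b <- array(runif(64), dim = c(8, 8, 1))
  expect_equal(frame_correlation(a, a), 1)
  expect_equal(frame_correlation(a, -(a - mean(a))), -1)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(frame_correlation(a, b), manual, tolerance = 1e-12)
  mask <- array(c(TRUE, FALSE), dim = dim(a))
  expect_equal(frame_correlation(a, b, mask),
               cor(a[mask], b[mask]), tolerance = 1e-12)
  expect_error(frame_correlation(a * 0, b), "undefined correlation")
})

test_that("series fitting logs per-frame results and resamples traces", {
  geom <- tiny_geometry(32L, 32L)
  tmpl <- array(make_test_image(32, 32, seed = 25), dim = c(32, 32, 1))
  frames <- list(tmpl,
                 warp_stack(tmpl, displacement_trace(rbind(c(1, 0), c(1, 0)),
                                                     geom$t_frame),
                            geom)$intensity)
  series <- fit_frame_series(frames, geom, reference = 1L, n_knots = 3L)
  expect_identical(nrow(series$log), 2L)
  expect_lt(mean(abs(series$fits[[2]]$trace$knots[, 1] + 1)), 0.25)

  tr <- displacement_trace(rbind(c(0, 0), c(2, 2), c(0, 0)), 100)
  rs <- resample_trace(tr, 5)
  expect_equal(rs$knots[, 1], c(0, 1, 2, 1, 0))
})
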
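#' Precompute the inverse-compositional reference model
#'
#' Everything in the Lucas-Kanade update that depends only on the template
#' is computed once: the smoothed template, its gradient images (central
#' differences), the steepest-descent images `grad(T) * dD/dp`, and the
#' Gauss-Newton Hessian `H = sum_voxels (grad(T) dD/dp)' (grad(T) dD/dp)`.
#' With the interleaved parameter ordering H is banded: a voxel's
#' displacement involves only two adjacent knots, so knots further than one
#' apart never couple and the band has `2d - 1` super-diagonals.
#'
#' Template and frames are scaled by the template's mean intensity before
#' fitting so the error is comparable across acquisitions.
#'
#' @param template `[n_y, n_x, n_z]` array (2D matrix promoted): the
#'   reference frame/stack.
#' @param n Number of displacement knots (`>= 2`).
#' @param geom A [scan_geometry()].
#' @param sigma_x Fast-axis smoothing sigma in pixels (default 2; the
#'   smoothing is used for estimation only).
#' @param d Displacement dimensionality; defaults to 3 for multi-slice
#'   stacks, else 2.
#' @return Object of class `reference_model` with elements `template`
#'   (smoothed, scaled), `template_raw`, `gradients`, `A` (sparse
#'   steepest-descent matrix, voxels x m), `H` (dense m x m), `H_band`
#'   (lower band storage), `kd` (super-diagonal count), `n`, `d`, `geom`,
#'   `sigma_x`, `norm`.
#' @export
precompute_reference <- function(template, n, geom, sigma_x = 2, d = NULL) {
  if (length(dim(template)) == 2) {
    template <- array(template, dim = c(dim(template), 1))
  }
  if (n < 2) stop("need at least 2 displacement knots")
  if (stats::sd(template) == 0) {
    stop("degenerate template: constant image carries no alignment information")
  }
  if (is.null(d)) d <- if (dim(template)[3] > 1) 3L else 2L
  tmpl_s <- smooth_fast_axis(template, sigma_x)
  norm <- mean(tmpl_s)
  if (norm <= 0) stop("degenerate template: non-positive mean intensity")
  tmpl_s <- tmpl_s / norm

  grad <- list(
    x = central_diff(tmpl_s, 2),
    y = central_diff(tmpl_s, 1)
  )
  if (d == 3) grad$z <- central_diff(tmpl_s, 3)

  J <- displacement_jacobian(geom, n, d)
  nv <- prod(dim(tmpl_s))
  # S: voxels x (voxels * d), S[v, (v-1)*d + i] = grad_i[v]
  gvals <- do.call(cbind, lapply(grad, as.vector))  # nv x d
  S <- Matrix::sparseMatrix(
    i = rep(seq_len(nv), times = d),
    j = as.vector(vapply(seq_len(d), function(i) (seq_len(nv) - 1L) * d + i,
                         numeric(nv))),
    x = as.vector(gvals),
    dims = c(nv, nv * d)
  )
  A <- S %*% J
  H <- as.matrix(Matrix::crossprod(A))
  kd <- 2L * d - 1L
  structure(list(
    template = tmpl_s, template_raw = template, gradients = grad,
    A = A, H = H, H_band = band_from_dense(H, kd), kd = kd,
    n = n, d = d, geom = geom, sigma_x = sigma_x, norm = norm
  ), class = "reference_model")
}

# Central-difference gradient along dimension `dim` (one-sided at borders).
central_diff <- function(arr, dim) {
  n <- dim(arr)[dim]
  if (n == 1) return(array(0, dim = dim(arr)))
  idx_p <- pmin(seq_len(n) + 1L, n)
  idx_m <- pmax(seq_len(n) - 1L, 1L)
  sc <- 1 / (idx_p - idx_m)
  if (dim == 1) {
    (arr[idx_p, , , drop = FALSE] - arr[idx_m, , , drop = FALSE]) * sc
  } else if (dim == 2) {
    sweep(arr[, idx_p, , drop = FALSE] - arr[, idx_m, , drop = FALSE],
          2, sc, "*")
  } else {
    sweep(arr[, , idx_p, drop = FALSE] - arr[, , idx_m, drop = FALSE],
          3, sc, "*")
  }
}

#' Registration error and inverse-compositional gradient
#'
#' The sum-of-squares error between the warped frame and the template over
#' mutually valid voxels, and its gradient with respect to the knot
#' parameters using the precomputed steepest-descent images:
#' `g = 2 * A' r`. Voxels whose warped sample falls outside the frame are
#' excluded from both sums; the valid-voxel count is returned so callers
#' can compare errors across displacements on a per-voxel basis (the
#' optimiser accepts steps on the mean, not the raw sum, so shrinking the
#' valid region is never rewarded).
#'
#' @param model A [precompute_reference()] result.
#' @param frame Smoothed, scaled frame array (same shape as the template);
#'   see [estimate_frame_motion()] for the driver that prepares it.
#' @param p Parameter vector (length `n * d`, interleaved).
#' @return list(E, g, n_valid).
#' @export
error_and_gradient <- function(model, frame, p) {
  trace <- trace_from_parameters(p, model$n, model$d, model$geom$t_frame)
  w <- warp_stack(frame, trace, model$geom)
  if (!any(w$valid_mask)) {
    stop("degenerate overlap: no valid voxels between warped frame and template")
  }
  res <- (w$intensity - model$template) * w$valid_mask
  E <- sum(res^2)
  g <- 2 * as.numeric(Matrix::crossprod(model$A, as.vector(res)))
  list(E = E, g = g, n_valid = sum(w$valid_mask))
}

#' Solve the trust-region subproblem on a banded Hessian
#'
#' Minimises the local quadratic model `m(s) = g's + s' H s` subject to
#' `||s|| <= delta` (the curvature `2H` is the Gauss-Newton Hessian of the
#' squared error). When the Newton step lies inside the region it is
#' returned exactly; otherwise the boundary solution is found by the
#' Newton root iteration on the secular equation, with every linear solve
#' performed through the banded Cholesky factorisation.
#'
#' @param H Dense symmetric `m x m` model matrix (as stored in a
#'   `reference_model`), or a lower band storage matrix.
#' @param g Gradient vector (length m).
#' @param delta Trust-region radius (`> 0`).
#' @param kd Number of super-diagonals when `H` is dense (defaults to the
#'   full bandwidth found in `H`).
#' @return The step `s` (numeric vector, `||s|| <= delta * (1 + 1e-6)`).
#' @export
trust_region_step <- function(H, g, delta, kd = NULL) {
  if (delta <= 0) stop("trust-region radius must be positive")
  m <- length(g)
  if (all(g == 0)) return(numeric(m))
  if (is.matrix(H) && nrow(H) == m && ncol(H) == m) {
    if (is.null(kd)) kd <- m - 1L
    ab <- band_from_dense(2 * H, kd)   # curvature of the quadratic model
  } else {
    ab <- H
    ab[1, ] <- 2 * ab[1, ]; ab[-1, ] <- 2 * ab[-1, ]
  }
  lambda0 <- 1e-9 * sum(ab[1, ]) / m
  # try the unconstrained Newton step first
  L <- tryCatch(band_chol(ab), error = function(e) NULL)
  if (is.null(L)) {
    L <- tryCatch(band_chol(band_shift(ab, lambda0)), error = function(e) NULL)
  }
  if (!is.null(L)) {
    s <- band_chol_solve(L, -g)
    ns <- sqrt(sum(s^2))
    if (ns <= delta) return(s)
  }
  # boundary solution: find lambda >= 0 with ||s(lambda)|| = delta
  lambda <- if (is.null(L)) max(lambda0, 1e-8) else 0
  for (iter in 1:50) {
    Ls <- tryCatch(band_chol(band_shift(ab, lambda)), error = function(e) NULL)
    if (is.null(Ls)) {
      lambda <- max(2 * lambda, lambda + lambda0, 1e-8)
      next
    }
    s <- band_chol_solve(Ls, -g)
    ns <- sqrt(sum(s^2))
    if (abs(ns - delta) <= 1e-6 * delta) return(s)
    w <- band_forward_solve(Ls, s)
    nw2 <- sum(w^2)
    dl <- (ns / sqrt(nw2))^2 * ((ns - delta) / delta)
    lambda <- max(lambda + dl, lambda * 1e-3, 0)
    if (!is.finite(lambda)) {
      stop("trust-region solve failed: non-finite regularisation")
    }
  }
  # fall back to the last feasible-scaled step
  s * (delta / sqrt(sum(s^2)))
}

#' Pearson correlation between frames over a validity mask
#'
#' The frame-quality metric: correlation between a (motion-corrected)
#' frame and the reference over the voxels both sampled.
#'
#' @param warped,template Arrays of equal shape.
#' @param mask Logical array of the same shape (default: all voxels).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
frame_correlation <- function(warped, template, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(warped))
  a <- as.vector(warped)[as.vector(mask)]
  b <- as.vector(template)[as.vector(mask)]
  if (length(a) < 2) stop("need at least 2 valid voxels for a correlation")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: image constant over the mask")
  }
  stats::cor(a, b)
}

#' Estimate the displacement trace of one frame
#'
#' Inverse-compositional Lucas-Kanade fit of the piecewise-linear motion
#' of a single frame against the reference model. Two starting points are
#' evaluated -- the null displacement and a rigid shift from windowed
#' phase correlation applied to every knot -- and the lower-error start is
#' refined by trust-region iterations (`p <- p + s`, Gauss-Newton model,
#' banded solves) until the relative change in the error drops below
#' `tol`. Non-convergence returns the best result found, flagged, rather
#' than an error.
#'
#' @param model A [precompute_reference()] result.
#' @param frame Raw (unsmoothed) frame array matching the template shape.
#' @param geom A [scan_geometry()] (defaults to the model's).
#' @param init_trace Optional extra starting trace (e.g. from a coarser
#'   fit), resampled to the model's knot count if needed.
#' @param control List: `tol` (relative error-change threshold, default
#'   1e-6), `max_iter` (200), `delta0` (initial radius, default
#'   `sqrt(m)` px), `delta_max` (image diagonal).
#' @return Object of class `lk_fit`: `trace`, `E`, `r` (correlation on the
#'   smoothed basis used for thresholds), `r_raw` (unsmoothed), `n_iterations`,
#'   `converged`, `init_used` ("null", "rigid" or "given").
#' @export
estimate_frame_motion <- function(model, frame, geom = model$geom,
                                  init_trace = NULL, control = list()) {
  ctl <- utils::modifyList(list(
    tol = 1e-6, max_iter = 200L, delta0 = NULL, delta_max = NULL,
    eta = 1e-4
  ), control)
  if (length(dim(frame)) == 2) frame <- array(frame, dim = c(dim(frame), 1))
  if (!identical(dim(frame), dim(model$template_raw))) {
    stop("frame shape does not match the reference model")
  }
  n <- model$n; d <- model$d; m <- n * d
  frame_s <- smooth_fast_axis(frame, model$sigma_x) / model$norm

  cand <- list(null = numeric(m))
  rigid <- tryCatch(phase_correlate(model$template, frame_s),
                    error = function(e) NULL)
  if (!is.null(rigid)) {
    cand$rigid <- as.vector(t(matrix(rigid[seq_len(d)], n, d, byrow = TRUE)))
  }
  if (!is.null(init_trace)) {
    tr <- if (init_trace$n != n) resample_trace(init_trace, n) else init_trace
    cand$given <- as_parameter_vector(tr)
  }
  evals <- lapply(cand, function(p) error_and_gradient(model, frame_s, p))
  # compare candidates on the per-valid-voxel mean: a large bogus shift
  # must not win simply by pushing voxels out of bounds
  best <- which.min(vapply(evals, function(e) e$E / e$n_valid, numeric(1)))
  p <- cand[[best]]
  eg <- evals[[best]]
  init_used <- names(cand)[best]

  delta <- if (is.null(ctl$delta0)) sqrt(m) else ctl$delta0
  delta_max <- if (is.null(ctl$delta_max)) {
    sqrt(sum(dim(frame)^2))
  } else ctl$delta_max
  converged <- FALSE
  iter <- 0L
  while (iter < ctl$max_iter) {
    iter <- iter + 1L
    s <- trust_region_step(model$H_band, eg$g, delta)
    pred <- -(sum(eg$g * s) + sum(s * (model$H %*% s))) / eg$n_valid
    if (pred <= 0) { converged <- TRUE; break }
    eg_new <- error_and_gradient(model, frame_s, p + s)
    # progress is judged on the mean residual per valid voxel, so steps
    # that merely shrink the overlap with the template are rejected
    rho <- (eg$E / eg$n_valid - eg_new$E / eg_new$n_valid) / pred
    if (rho >= ctl$eta) {
      dE <- eg$E / eg$n_valid - eg_new$E / eg_new$n_valid
      p <- p + s
      eg <- eg_new
      if (dE < ctl$tol * max(1, eg$E / eg$n_valid)) { converged <- TRUE; break }
    }
    if (rho < 0.25) {
      delta <- 0.25 * delta
    } else if (rho > 0.75 && sqrt(sum(s^2)) >= 0.99 * delta) {
      delta <- min(2 * delta, delta_max)
    }
    if (delta < 1e-8) { converged <- TRUE; break }
  }

  # correlations over the full template support: unsampled voxels read 0,
  # so quality cannot be inflated by discarding image area
  trace <- trace_from_parameters(p, n, d, geom$t_frame)
  w_s <- warp_stack(frame_s, trace, geom)
  r_s <- tryCatch(
    frame_correlation(w_s$intensity, model$template),
    error = function(e) NA_real_)
  w_r <- warp_stack(frame, trace, geom)
  r_raw <- tryCatch(
    frame_correlation(w_r$intensity, model$template_raw),
    error = function(e) NA_real_)
  structure(list(trace = trace, E = eg$E, r = r_s, r_raw = r_raw,
                 n_iterations = iter, converged = converged,
                 init_used = init_used),
            class = "lk_fit")
}

#' @export
print.lk_fit <- function(x, ...) {
  cat(sprintf("lk_fit: E = %.4g, r = %.4f (raw %.4f), %d iter, init %s%s\n",
              x$E, x$r, x$r_raw, x$n_iterations, x$init_used,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Resample a displacement trace to a different knot count
#'
#' Evaluates the piecewise-linear trace at `n_new` equally spaced knot
#' times over the same frame period (used to hand a coarse fit to a finer
#' model).
#'
#' @param trace A [displacement_trace()].
#' @param n_new New knot count.
#' @export
resample_trace <- function(trace, n_new) {
  tt <- seq(0, trace$t_frame, length.out = n_new)
  displacement_trace(displacement_at(trace, tt), trace$t_frame)
}

#' Fit displacement traces for every frame of a series
#'
#' The per-series driver: builds the reference model from a user-selected
#' frame, then estimates each frame's trace. An optional knot-count
#' schedule fits each frame coarse-to-fine (each stage initialising the
#' next), which extends the capture range for large motions.
#'
#' @param frames List of `[n_y, n_x, n_z]` arrays ([reconstruct_frames()]).
#' @param geom A [scan_geometry()].
#' @param reference 1-based index of the reference frame (default 1), or an
#'   array to register against (e.g. an externally supplied template).
#' @param n_knots Final knot count (default 10, suited to 256 x 256
#'   frames).
#' @param sigma_x Fast-axis smoothing for estimation (default 2 px).
#' @param schedule Knot counts for coarse-to-fine stages before `n_knots`.
#'   The default adds one half-resolution stage when `n_knots >= 8`, which
#'   extends the capture range for large or fast motions; `NULL` disables
#'   staging.
#' @param control Passed to [estimate_frame_motion()].
#' @return Object of class `lk_series`: list with `fits` (per-frame
#'   `lk_fit`), `log` (data.frame: frame, init, iterations, E, r, r_raw,
#'   converged), `model` (final reference model), `reference`.
#' @export
fit_frame_series <- function(frames, geom, reference = 1L, n_knots = 10L,
                             sigma_x = 2,
                             schedule = if (n_knots >= 8) round(n_knots / 2),
                             control = list()) {
  if (n_knots < 2) stop("n_knots must be at least 2")
  ref_img <- if (is.numeric(reference) && length(reference) == 1) {
    frames[[reference]]
  } else {
    reference
  }
  stages <- unique(c(schedule, n_knots))
  if (is.unsorted(stages)) stop("knot schedule must be increasing")
  models <- lapply(stages, function(nk) {
    precompute_reference(ref_img, nk, geom, sigma_x = sigma_x)
  })
  fits <- vector("list", length(frames))
  coarse_control <- utils::modifyList(control, list(tol = 1e-4))
  for (f in seq_along(frames)) {
    # the previous frame's trace seeds the first stage: sample motion is
    # continuous across frames, so it is often the best starting candidate
    init <- if (f > 1) fits[[f - 1]]$trace else NULL
    for (si in seq_along(stages)) {
      ctl <- if (si < length(stages)) coarse_control else control
      fit <- estimate_frame_motion(models[[si]], frames[[f]],
                                   init_trace = init, control = ctl)
      init <- fit$trace
    }
    fits[[f]] <- fit
  }
  log <- data.frame(
    frame = seq_along(frames),
    init = vapply(fits, `[[`, character(1), "init_used"),
    iterations = vapply(fits, `[[`, integer(1), "n_iterations"),
    E = vapply(fits, `[[`, numeric(1), "E"),
    r = vapply(fits, `[[`, numeric(1), "r"),
    r_raw = vapply(fits, `[[`, numeric(1), "r_raw"),
    converged = vapply(fits, `[[`, logical(1), "converged")
  )
  structure(list(fits = fits, log = log,
                 model = models[[length(models)]],
                 reference = reference),
            class = "lk_series")
}

#' @export
print.lk_series <- function(x, ...) {
  cat(sprintf("lk_series: %d frames, mean r = %.4f (%d converged)\n",
              nrow(x$log), mean(x$log$r, na.rm = TRUE), sum(x$log$converged)))
  invisible(x)
}

#' Total optimisation parameter count of a stack series
#'
#' For a time series of `n_stacks` stacks each fitted with `n_knots`
#' displacement knots in `d` dimensions, the optimiser handles
#' `n_stacks * n_knots * d` parameters in total.
#'
#' @param n_stacks,n_knots,d Integers.
#' @export
series_parameter_count <- function(n_stacks, n_knots, d) {
  as.integer(n_stacks) * as.integer(n_knots) * as.integer(d)
}
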
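#' Piecewise-linear displacement trace
#'
#' The motion model: `n` displacement knots `r(i)` (in pixels, 2 or 3
#' dimensions) equally spaced over the frame period, with the sample
#' assumed to move linearly between knots. Knot `i` (0-based) sits at time
#' `t_i = i * t_frame / (n - 1)`; both endpoints are included so traces of
#' consecutive frames meet continuously.
#'
#' The sign convention throughout the package: `D(t)` is the apparent
#' scene shift at scan time `t`, such that sampling the recorded frame at
#' `q + D(t(q))` reproduces the reference at pixel `q` (the estimation
#' warp, [warp_stack()]), and a photon recorded at pixel `q` is restored
#' to `q - D(t)` ([reassign_photons()]).
#'
#' @param knots `n x d` numeric matrix of displacements in pixels, columns
#'   ordered (x, y\[, z\]).
#' @param t_frame Frame (or stack) period in macro ticks that the knots
#'   span.
#' @return Object of class `displacement_trace`.
#' @export
displacement_trace <- function(knots, t_frame) {
  knots <- as.matrix(knots)
  if (nrow(knots) < 2) stop("need at least 2 displacement knots")
  if (!ncol(knots) %in% c(2L, 3L)) stop("displacements must be 2- or 3-dimensional")
  if (!all(is.finite(knots))) stop("displacement knots must be finite")
  if (t_frame <= 0) stop("t_frame must be positive")
  structure(list(knots = unname(knots), t_frame = t_frame,
                 n = nrow(knots), d = ncol(knots)),
            class = "displacement_trace")
}

#' Zero displacement trace
#' @param n Number of knots.
#' @param d Dimensions (2 or 3).
#' @param t_frame Frame period in ticks.
#' @export
zero_trace <- function(n, d, t_frame) {
  displacement_trace(matrix(0, n, d), t_frame)
}

#' Flatten / restore the optimisation parameter vector
#'
#' Parameters are interleaved per knot:
#' `p = (rx(1), ry(1)[, rz(1)], rx(2), ...)`, length `m = n * d`. This
#' ordering makes the Lucas-Kanade Hessian banded (adjacent knots only).
#'
#' @param trace A [displacement_trace()].
#' @return `as_parameter_vector()`: numeric vector of length `n * d`.
#' @export
as_parameter_vector <- function(trace) {
  as.vector(t(trace$knots))
}

#' @rdname as_parameter_vector
#' @param p Parameter vector of length `n * d`.
#' @param n,d Knot count and dimensionality.
#' @param t_frame Frame period in ticks.
#' @export
trace_from_parameters <- function(p, n, d, t_frame) {
  displacement_trace(matrix(p, nrow = n, ncol = d, byrow = TRUE), t_frame)
}

# Segment index k (0-based) and within-segment weight w for times t.
trace_segment <- function(t, n, t_frame) {
  t <- pmin(pmax(t, 0), t_frame)
  s <- t * (n - 1) / t_frame
  k <- pmin(floor(s), n - 2)
  list(k = k, w = s - k)
}

#' Evaluate a displacement trace
#'
#' Piecewise-linear interpolation of the knots:
#' `D(t) = r(k) + (r(k+1) - r(k)) * (t - t_k)(n-1)/t_frame`.
#' Times outside `[0, t_frame]` are clamped to the nearest endpoint with a
#' warning.
#'
#' @param trace A [displacement_trace()].
#' @param t Macro times (ticks) relative to the frame start; vectorised.
#' @return `length(t) x d` matrix of displacements in pixels.
#' @export
displacement_at <- function(trace, t) {
  if (any(t < 0 | t > trace$t_frame)) {
    warning("times outside [0, t_frame] clamped to the nearest endpoint")
  }
  seg <- trace_segment(t, trace$n, trace$t_frame)
  (1 - seg$w) * trace$knots[seg$k + 1, , drop = FALSE] +
    seg$w * trace$knots[seg$k + 2, , drop = FALSE]
}

# Vectorised bi/trilinear sampling of arr [y, x, z] at fractional 0-based
# coordinates; returns list(values, valid). Out-of-bounds samples are 0 and
# invalid (never clamped: clamping would bias the optimiser toward edges).
interp_sample <- function(arr, xq, yq, zq = NULL) {
  dims <- dim(arr)
  n_y <- dims[1]; n_x <- dims[2]; n_z <- dims[3]
  if (is.null(zq)) zq <- rep(0, length(xq))
  x0 <- floor(xq); y0 <- floor(yq); z0 <- floor(zq)
  fx <- xq - x0; fy <- yq - y0; fz <- zq - z0
  if (n_z == 1) { z0 <- pmin(z0, 0); fz <- fz * 0 }

  valid <- x0 >= 0 & x0 <= n_x - 1 & (x0 < n_x - 1 | fx == 0) &
           y0 >= 0 & y0 <= n_y - 1 & (y0 < n_y - 1 | fy == 0) &
           z0 >= 0 & z0 <= n_z - 1 & (z0 < n_z - 1 | fz == 0)

  v <- numeric(length(xq))
  if (any(valid)) {
    x0v <- x0[valid]; y0v <- y0[valid]; z0v <- z0[valid]
    fxv <- fx[valid]; fyv <- fy[valid]; fzv <- fz[valid]
    x1 <- pmin(x0v + 1, n_x - 1); y1 <- pmin(y0v + 1, n_y - 1)
    z1 <- pmin(z0v + 1, n_z - 1)
    at <- function(xx, yy, zz) arr[zz * (n_y * n_x) + xx * n_y + yy + 1]
    c00 <- at(x0v, y0v, z0v) * (1 - fxv) + at(x1, y0v, z0v) * fxv
    c10 <- at(x0v, y1, z0v) * (1 - fxv) + at(x1, y1, z0v) * fxv
    c0 <- c00 * (1 - fyv) + c10 * fyv
    if (n_z > 1) {
      c01 <- at(x0v, y0v, z1) * (1 - fxv) + at(x1, y0v, z1) * fxv
      c11 <- at(x0v, y1, z1) * (1 - fxv) + at(x1, y1, z1) * fxv
      c1 <- c01 * (1 - fyv) + c11 * fyv
      c0 <- c0 * (1 - fzv) + c1 * fzv
    }
    v[valid] <- c0
  }
  list(values = v, valid = valid)
}

#' Warp a frame by a displacement trace (estimation warp)
#'
#' Samples the input at `(x, y, z) + D(t(x, y, z))` by bi/trilinear
#' interpolation, where `t` is the raster acquisition time of each output
#' pixel. Samples falling outside the input are set to 0 and marked
#' invalid. This is the warp used inside the registration error function;
#' it is deliberately not intensity-preserving (every output pixel gets an
#' estimate, which keeps the error surface smooth). The final data are
#' instead rebuilt by photon reassignment.
#'
#' @param stack `[n_y, n_x, n_z]` array (2D matrices are promoted).
#' @param trace A [displacement_trace()].
#' @param geom A [scan_geometry()].
#' @return list with `intensity` (warped array) and `valid_mask`
#'   (logical array, TRUE where the sample landed inside the input).
#' @export
warp_stack <- function(stack, trace, geom) {
  if (length(dim(stack)) == 2) stack <- array(stack, dim = c(dim(stack), 1))
  tpx <- pixel_time_array(geom)
  D <- displacement_at(trace, as.vector(tpx))
  dims <- dim(stack)
  xq <- rep(rep(seq_len(dims[2]) - 1, each = dims[1]), times = dims[3]) + D[, 1]
  yq <- rep(seq_len(dims[1]) - 1, times = dims[2] * dims[3]) + D[, 2]
  zq <- rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2])
  if (trace$d == 3) zq <- zq + D[, 3]
  s <- interp_sample(stack, xq, yq, zq)
  list(intensity = array(s$values, dim = dims),
       valid_mask = array(s$valid, dim = dims))
}

#' Jacobian of the displacement field with respect to the knots
#'
#' For each voxel (raster time `t` in segment `[t_k, t_{k+1}]`) the
#' displacement depends on knots `k` and `k+1` only, with hat-function
#' weights `1 - (t - t_k)(n-1)/t_frame` and `(t - t_k)(n-1)/t_frame` in the
#' matching dimension and zeros across dimensions. Rows are ordered voxel
#' by voxel, `d` rows per voxel; columns follow the interleaved parameter
#' ordering. Per-dimension row weights sum to one (partition of unity).
#'
#' @param geom A [scan_geometry()].
#' @param n Number of knots (`>= 2`).
#' @param d Dimensions (2 or 3).
#' @param t_frame Period the knots span (default `geom$t_frame`).
#' @return Sparse `(n_vox * d) x (n * d)` matrix (`Matrix::sparseMatrix`).
#' @export
displacement_jacobian <- function(geom, n, d, t_frame = geom$t_frame) {
  if (n < 2) stop("need at least 2 knots")
  tpx <- as.vector(pixel_time_array(geom))
  seg <- trace_segment(tpx, n, t_frame)
  nv <- length(tpx)
  dims <- rep(seq_len(d), times = nv)           # dimension of each row
  vox <- rep(seq_len(nv), each = d)
  rows <- seq_len(nv * d)
  k <- rep(seg$k, each = d)                      # 0-based segment per row
  w <- rep(seg$w, each = d)
  col0 <- k * d + dims                           # knot k, matching dim
  col1 <- (k + 1) * d + dims
  Matrix::sparseMatrix(
    i = c(rows, rows), j = c(col0, col1), x = c(1 - w, w),
    dims = c(nv * d, n * d)
  )
}
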
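# Hanning window of length n (n == 1 degenerates to 1).
hanning1d <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# Separable 3D Hanning window matching dim(arr) = c(n_y, n_x, n_z).
hanning_window <- function(dims) {
  wy <- hanning1d(dims[1]); wx <- hanning1d(dims[2]); wz <- hanning1d(dims[3])
  array(as.vector(outer(outer(wy, wx), wz)), dim = dims)
}

# Wrap 0-based circular indices into signed shifts in (-N/2, N/2].
wrap_shift <- function(idx, n) {
  s <- idx
  s[s > n / 2] <- s[s > n / 2] - n
  s
}

# 3-point parabolic sub-pixel peak refinement along one axis using
# circular neighbours; returns the fractional offset in (-0.5, 0.5).
parabolic_offset <- function(ym, y0, yp) {
  den <- ym - 2 * y0 + yp
  if (abs(den) < .Machine$double.eps * max(1, abs(y0))) return(0)
  off <- 0.5 * (ym - yp) / den
  max(min(off, 0.5), -0.5)
}

# Circularly shift array content by integer (y, x, z): out[q] = a[q - s].
circular_shift <- function(a, s) {
  dims <- dim(a)
  idx <- lapply(1:3, function(ax) {
    ((seq_len(dims[ax]) - 1 - s[ax]) %% dims[ax]) + 1
  })
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# Single pass of windowed phase correlation; returns (sy, sx, sz).
phase_correlate_once <- function(ref, mov) {
  dims <- dim(ref)
  w <- hanning_window(dims)
  fa <- stats::fft(ref * w)
  fb <- stats::fft(mov * w)
  cp <- fa * Conj(fb)
  r <- cp / (Mod(cp) + 1e-12)
  corr <- Re(stats::fft(r, inverse = TRUE)) / length(r)
  peak <- arrayInd(which.max(corr), dims)[1, ]
  off <- numeric(3)
  for (ax in 1:3) {
    if (dims[ax] == 1) next
    im <- peak; im[ax] <- ((peak[ax] - 2) %% dims[ax]) + 1
    ip <- peak; ip[ax] <- (peak[ax] %% dims[ax]) + 1
    off[ax] <- parabolic_offset(corr[rbind(im)], corr[rbind(peak)],
                                corr[rbind(ip)])
  }
  loc <- (peak - 1) + off
  # ifft(FA o Conj(FB)) peaks at -s under mov(q) = ref(q - s)
  -mapply(wrap_shift, loc, dims)
}

#' Rigid shift estimate by windowed phase correlation
#'
#' Coarse translation between two equally shaped stacks: both are
#' multiplied by a separable Hanning window to suppress edge artefacts, the
#' normalised cross-power spectrum `R = F_A * Conj(F_B) / |F_A * Conj(F_B)|`
#' is inverted, and the correlation peak is located to sub-pixel precision
#' by a separable 3-point parabolic fit. When the estimate has an integer
#' part, it is removed by circularly shifting `mov` and the small residual
#' re-estimated in a second pass (the windowed parabola is most accurate
#' near zero shift). Shifts are wrapped into `(-N/2, N/2]` per axis. 2D
#' inputs are handled as a single-slice stack.
#'
#' The returned shift `s` follows the package warp convention: `mov`
#' equals `ref` translated by `+s`, i.e. `mov(q) ~ ref(q - s)`, so `s` is
#' directly usable as a constant displacement-trace initialiser.
#'
#' @param ref,mov Arrays `[n_y, n_x, n_z]` (or 2D matrices) of equal shape.
#' @return Numeric shift `(sx, sy, sz)` in pixels (length 3; `sz = 0` for
#'   single-slice input).
#' @export
phase_correlate <- function(ref, mov) {
  if (length(dim(ref)) == 2) ref <- array(ref, dim = c(dim(ref), 1))
  if (length(dim(mov)) == 2) mov <- array(mov, dim = c(dim(mov), 1))
  if (!identical(dim(ref), dim(mov))) stop("stacks must have equal shapes")
  if (stats::sd(ref) == 0 || stats::sd(mov) == 0) {
    stop("degenerate input: constant image has no correlation peak")
  }
  s1 <- phase_correlate_once(ref, mov)
  si <- round(s1)
  s <- if (any(si != 0)) {
    si + phase_correlate_once(ref, circular_shift(mov, -si))
  } else {
    s1
  }
  c(s[2], s[1], s[3])
}
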
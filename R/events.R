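#' Marker kind codes
#'
#' Integer codes used for scan markers in TTTR event streams and in the
#' on-disk container: `1` = line start, `2` = line end, `4` = frame start.
#' @name marker_kinds
#' @export
MARKER_LINE_START <- 1L
#' @rdname marker_kinds
#' @export
MARKER_LINE_END <- 2L
#' @rdname marker_kinds
#' @export
MARKER_FRAME_START <- 4L

#' Time-tagged photon event stream
#'
#' A TTTR (time-tagged time-resolved) stream: photon events carrying a
#' coarse macro time (experiment clock ticks), a micro time (bins since
#' the last excitation pulse) and a spectral channel index, interleaved
#' with frame-start and line start/end markers that tie macro time to the
#' raster scan position.
#'
#' @param photons data.frame with columns `macro_time` (numeric ticks,
#'   non-decreasing), `micro_time` (integer bins) and `channel`
#'   (integer, 0-based).
#' @param markers data.frame with columns `macro_time` and `kind`
#'   (see [marker_kinds]).
#' @param geometry Optional [scan_geometry()] carried with the stream.
#' @return An object of class `tttr_stream`.
#' @export
tttr_stream <- function(photons, markers, geometry = NULL) {
  need_p <- c("macro_time", "micro_time", "channel")
  if (!all(need_p %in% names(photons))) {
    stop("photons must have columns macro_time, micro_time, channel")
  }
  if (!all(c("macro_time", "kind") %in% names(markers))) {
    stop("markers must have columns macro_time, kind")
  }
  bad <- which(diff(photons$macro_time) < 0)
  if (length(bad)) {
    stop(sprintf("photon macro times not non-decreasing at index %d", bad[1] + 1L))
  }
  bad <- which(diff(markers$macro_time) < 0)
  if (length(bad)) {
    stop(sprintf("marker macro times not non-decreasing at index %d", bad[1] + 1L))
  }
  structure(list(photons = photons, markers = markers, geometry = geometry),
            class = "tttr_stream")
}

#' @export
print.tttr_stream <- function(x, ...) {
  nf <- sum(x$markers$kind == MARKER_FRAME_START)
  cat(sprintf("tttr_stream: %d photons, %d markers (%d frames)\n",
              nrow(x$photons), nrow(x$markers), nf))
  invisible(x)
}

#' Number of frames in a stream
#' @param stream A [tttr_stream()].
#' @return Count of FRAME_START markers.
#' @export
n_frames <- function(stream) {
  sum(stream$markers$kind == MARKER_FRAME_START)
}

#' Assign photons to raster pixels
#'
#' Bins each photon into a pixel from the line markers alone: the x
#' coordinate is `floor((macro - line_start) / t_pixel)` (half-open bins,
#' clipped to the line), y is the line count since the frame start, z the
#' slice count, and the frame index comes from the preceding FRAME_START.
#' Photons arriving before the first frame or during retrace (between a
#' LINE_END and the next LINE_START) are flagged unassigned, not dropped
#' with an error.
#'
#' @param stream A [tttr_stream()].
#' @param geom A [scan_geometry()].
#' @return data.frame with one row per photon: 0-based `x`, `y`, `z`,
#'   0-based `frame`, logical `assigned`, and `t_rel` (macro time relative
#'   to the frame start). Unassigned photons have NA coordinates.
#' @export
assign_pixels <- function(stream, geom) {
  ph <- stream$photons
  mk <- stream$markers
  fs <- mk$macro_time[mk$kind == MARKER_FRAME_START]
  ls <- mk$macro_time[mk$kind == MARKER_LINE_START]
  le <- mk$macro_time[mk$kind == MARKER_LINE_END]
  if (length(ls) != length(le)) {
    stop("unpaired line markers: LINE_START and LINE_END counts differ")
  }
  if (any(le < ls)) stop("LINE_END precedes matching LINE_START")
  np <- nrow(ph)
  t <- ph$macro_time

  line_idx <- findInterval(t, ls)                  # 0 if before first line
  frame_idx <- findInterval(t, fs)                 # 0 if before first frame
  active <- line_idx >= 1L
  active[active] <- t[active] < le[line_idx[active]]
  assigned <- active & frame_idx >= 1L

  # line number within its frame: count of line starts since the frame start
  # next line starting at/after the frame start (markers are integer ticks,
  # so the half-tick shift makes a coincident LINE_START count as inside)
  first_line_of_frame <- findInterval(fs - 0.5, ls) + 1L
  fl <- rep(NA_integer_, np)
  fl[assigned] <- first_line_of_frame[frame_idx[assigned]]
  line_in_frame <- line_idx - fl                   # 0-based

  y <- line_in_frame %% geom$n_y
  z <- line_in_frame %/% geom$n_y
  x <- rep(NA_real_, np)
  x[assigned] <- floor((t[assigned] - ls[line_idx[assigned]]) / geom$t_pixel)
  x <- pmin(pmax(x, 0), geom$n_x - 1)

  bad <- assigned & (z > geom$n_z - 1 | line_in_frame < 0)
  assigned[bad] <- FALSE
  x[!assigned] <- NA_real_
  y[!assigned] <- NA_integer_
  z[!assigned] <- NA_integer_
  t_rel <- rep(NA_real_, np)
  t_rel[assigned] <- t[assigned] - fs[frame_idx[assigned]]
  frame0 <- ifelse(assigned, frame_idx - 1L, NA_integer_)

  data.frame(x = as.integer(x), y = as.integer(y), z = as.integer(z),
             frame = as.integer(frame0), assigned = assigned, t_rel = t_rel)
}

#' Reconstruct per-frame intensity images from a photon stream
#'
#' Histograms assigned photons into per-frame voxel counts, disregarding
#' micro-time information. Photon conservation holds: the summed intensity
#' over all frames equals the number of assigned photons; the unassigned
#' (pre-scan / retrace) count is attached as an attribute.
#'
#' @param stream A [tttr_stream()].
#' @param geom A [scan_geometry()].
#' @param n_frames Optional frame count (default: number of FRAME_START
#'   markers).
#' @return List of `[n_y, n_x, n_z]` count arrays, one per frame, with
#'   attribute `n_unassigned`.
#' @export
reconstruct_frames <- function(stream, geom, n_frames = NULL) {
  if (is.null(n_frames)) n_frames <- sum(stream$markers$kind == MARKER_FRAME_START)
  if (n_frames < 1) stop("stream contains no frames")
  px <- assign_pixels(stream, geom)
  keep <- px$assigned & px$frame < n_frames
  nvox <- geom$n_y * geom$n_x * geom$n_z
  idx <- px$frame[keep] * nvox +
    px$z[keep] * (geom$n_y * geom$n_x) +
    px$x[keep] * geom$n_y + px$y[keep] + 1
  counts <- tabulate(idx, nbins = nvox * n_frames)
  frames <- lapply(seq_len(n_frames), function(f) {
    array(counts[((f - 1) * nvox + 1):(f * nvox)],
          dim = c(geom$n_y, geom$n_x, geom$n_z))
  })
  attr(frames, "n_unassigned") <- sum(!px$assigned)
  frames
}

# Discrete Gaussian kernel; sigma = 0 gives the identity kernel.
gauss_kernel1d <- function(sigma) {
  if (sigma < 0) stop("smoothing sigma must be non-negative")
  if (sigma == 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

# Convolve an [y, x, z] array along dimension `dim` (1 = y, 2 = x) with a
# centred odd-length kernel, zero-padded at the boundary.
convolve_dim <- function(arr, kernel, dim) {
  nk <- length(kernel)
  if (nk == 1) return(arr * kernel)
  r <- (nk - 1) %/% 2
  out <- array(0, dim = dim(arr))
  n <- dim(arr)[dim]
  for (j in seq_len(nk)) {
    off <- j - r - 1L
    src <- seq_len(n) + off
    ok <- src >= 1 & src <= n
    if (!any(ok)) next
    dst <- which(ok)
    if (dim == 1) {
      out[dst, , ] <- out[dst, , , drop = FALSE] +
        kernel[j] * arr[src[ok], , , drop = FALSE]
    } else if (dim == 2) {
      out[, dst, ] <- out[, dst, , drop = FALSE] +
        kernel[j] * arr[, src[ok], , drop = FALSE]
    } else {
      out[, , dst] <- out[, , dst, drop = FALSE] +
        kernel[j] * arr[, , src[ok], drop = FALSE]
    }
  }
  out
}

#' Elliptical Gaussian smoothing along the fast scan axis
#'
#' Applies the realignment pre-filter: a Gaussian of user-controlled width
#' `sigma_x` along the fast (x) axis and a fixed 1-pixel-radius Gaussian
#' along the slow (y) axis. Used only on copies taken for motion
#' estimation; the final reconstructed data are never smoothed. With
#' `sigma_x = 0` the fast axis is left untouched (the slow-axis kernel is
#' still applied).
#'
#' @param frame `[n_y, n_x, n_z]` array (a 2D matrix is promoted).
#' @param sigma_x Fast-axis Gaussian sigma in pixels, `>= 0`.
#' @param sigma_slow Slow-axis sigma in pixels (default 1).
#' @return Smoothed array of the same shape.
#' @export
smooth_fast_axis <- function(frame, sigma_x, sigma_slow = 1) {
  if (sigma_x < 0) stop("sigma_x must be non-negative")
  if (length(dim(frame)) == 2) frame <- array(frame, dim = c(dim(frame), 1))
  out <- convolve_dim(frame, gauss_kernel1d(sigma_x), dim = 2)
  convolve_dim(out, gauss_kernel1d(sigma_slow), dim = 1)
}
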
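#' Raster scan geometry
#'
#' Describes the timing and dimensions of a unidirectional raster scan:
#' how macro time (coarse experiment clock ticks) maps onto pixel
#' coordinates `(x, y, z)` and frame numbers. All durations are expressed
#' in macro-clock ticks and may be fractional (the pixel dwell time
#' `t_pixel = t_line / n_x` rarely lands on an integer tick).
#'
#' @param n_x,n_y,n_z Pixels per line, lines per slice and slices per
#'   frame/stack. 2D scans use `n_z = 1`.
#' @param t_line Active (acquiring) duration of one line, in ticks.
#' @param t_interline Retrace gap between the end of one line and the start
#'   of the next, in ticks. The line start-to-start period is
#'   `t_line + t_interline`.
#' @param t_frame Frame (or stack) start-to-start period in ticks. Defaults
#'   to `n_z * t_slice`, i.e. an inter-frame gap equal to the interline gap.
#' @param t_slice Slice start-to-start period in ticks; defaults to
#'   `n_y * (t_line + t_interline)`.
#' @param n_channels Number of spectral channels.
#' @param macro_resolution Seconds per macro tick.
#' @param micro_resolution Seconds per micro-time bin.
#' @param rep_period Laser repetition period in seconds.
#'
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(n_x, n_y, n_z = 1L,
                          t_line, t_interline,
                          t_slice = NULL, t_frame = NULL,
                          n_channels = 1L,
                          macro_resolution = 1e-7,
                          micro_resolution = 12.5e-9 / 256,
                          rep_period = 12.5e-9) {
  if (n_x < 1 || n_y < 1 || n_z < 1) stop("image dimensions must be positive")
  if (t_line <= 0 || t_interline < 0) stop("line timings must be positive")
  if (is.null(t_slice)) t_slice <- n_y * (t_line + t_interline)
  if (is.null(t_frame)) t_frame <- n_z * t_slice
  slack <- 1e-3 * (t_line + t_interline)  # tolerate marker jitter
  if (t_slice < n_y * (t_line + t_interline) - slack) {
    stop("t_slice shorter than the lines it contains")
  }
  if (t_frame < n_z * t_slice - slack) {
    stop("t_frame shorter than the slices it contains")
  }
  structure(list(
    n_x = as.integer(n_x), n_y = as.integer(n_y), n_z = as.integer(n_z),
    t_pixel = t_line / n_x,
    t_line = t_line, t_interline = t_interline,
    t_slice = t_slice, t_frame = t_frame,
    n_channels = as.integer(n_channels),
    macro_resolution = macro_resolution,
    micro_resolution = micro_resolution,
    rep_period = rep_period
  ), class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("scan_geometry: %d x %d x %d, %d channel(s)\n",
              x$n_x, x$n_y, x$n_z, x$n_channels))
  cat(sprintf("  t_pixel %.3f  t_line %.1f  t_interline %.1f ticks\n",
              x$t_pixel, x$t_line, x$t_interline))
  cat(sprintf("  t_slice %.1f  t_frame %.1f ticks  (%.4g s/tick)\n",
              x$t_slice, x$t_frame, x$macro_resolution))
  invisible(x)
}

#' Macro time of a pixel within its frame
#'
#' Raster-time map: the acquisition time of pixel `(x, y, z)` relative to
#' the frame start, `t = x * t_pixel + y * (t_line + t_interline) +
#' z * t_slice`. Coordinates are 0-based; pixel `(0, 0, 0)` maps to 0.
#' For multi-slice stacks the z term uses the slice start-to-start period.
#'
#' @param x,y,z 0-based pixel coordinates (vectors recycle).
#' @param geom A [scan_geometry()].
#' @return Macro time(s) in ticks, at the start of the pixel dwell.
#' @export
pixel_macro_time <- function(x, y, z = 0, geom) {
  if (any(x < 0 | x >= geom$n_x) || any(y < 0 | y >= geom$n_y) ||
      any(z < 0 | z >= geom$n_z)) {
    stop("pixel coordinates outside scan geometry")
  }
  x * geom$t_pixel + y * (geom$t_line + geom$t_interline) + z * geom$t_slice
}

# Pixel start times for every voxel, as an array [y, x, z] in ticks.
pixel_time_array <- function(geom) {
  x <- rep(rep(seq_len(geom$n_x) - 1, each = geom$n_y), times = geom$n_z)
  y <- rep(seq_len(geom$n_y) - 1, times = geom$n_x * geom$n_z)
  z <- rep(seq_len(geom$n_z) - 1, each = geom$n_x * geom$n_y)
  array(x * geom$t_pixel + y * (geom$t_line + geom$t_interline) +
          z * geom$t_slice,
        dim = c(geom$n_y, geom$n_x, geom$n_z))
}

#' Infer raster timing from scan markers
#'
#' Recovers line, interline and frame periods from the frame/line markers of
#' an event stream: `t_line` is the median LINE_END - LINE_START interval,
#' the interline gap is the median line start-to-start interval minus
#' `t_line`, and the frame period is the median FRAME_START interval.
#' Medians make the estimates robust to marker jitter.
#'
#' @param stream A [tttr_stream()].
#' @param n_x,n_y,n_z Image dimensions (not encoded in the markers).
#' @param ... Passed on to [scan_geometry()] (resolutions, channels).
#' @return A [scan_geometry()].
#' @export
infer_scan_timing <- function(stream, n_x, n_y, n_z = 1L, ...) {
  mk <- stream$markers
  fs <- mk$macro_time[mk$kind == MARKER_FRAME_START]
  if (length(fs) < 2) stop("insufficient data: need at least 2 frames of markers")
  ls <- mk$macro_time[mk$kind == MARKER_LINE_START]
  le <- mk$macro_time[mk$kind == MARKER_LINE_END]
  if (length(ls) < 2 || length(le) < 1) stop("insufficient data: too few line markers")
  n <- min(length(ls), length(le))
  t_line <- stats::median(le[seq_len(n)] - ls[seq_len(n)])
  # start-to-start within a frame only: drop intervals spanning a frame gap
  d_ls <- diff(ls)
  per_frame <- findInterval(ls, fs)
  same <- diff(per_frame) == 0
  t_s2s <- stats::median(d_ls[same])
  t_frame <- stats::median(diff(fs))
  scan_geometry(n_x = n_x, n_y = n_y, n_z = n_z,
                t_line = t_line, t_interline = t_s2s - t_line,
                t_slice = t_frame / n_z, t_frame = t_frame, ...)
}
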
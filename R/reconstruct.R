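round_half_up <- function(v) floor(v + 0.5)

# Normalise the per-frame trace argument: a single trace is recycled,
# otherwise one trace per frame is required.
check_traces <- function(traces, nf) {
  if (inherits(traces, "displacement_trace")) traces <- list(traces)
  if (length(traces) == 1L) traces <- rep(traces, nf)
  if (length(traces) != nf) {
    stop(sprintf("configuration error: %d frames but %d displacement traces",
                 nf, length(traces)))
  }
  traces
}

frames_to_keep <- function(nf, r_values, r_thresh) {
  if (is.null(r_thresh)) return(seq_len(nf))
  if (is.null(r_values) || length(r_values) != nf) {
    stop("configuration error: r_thresh set but no per-frame r values")
  }
  which(!is.na(r_values) & r_values >= r_thresh)
}

#' Reassign photons using fitted displacement traces
#'
#' The intensity-preserving reconstruction: every photon recorded at pixel
#' `(x, y, z)` at macro time `t` (relative to its frame start) is moved to
#' the rounded coordinate `(x - Dx(t), y - Dy(t), z - Dz(t))` using that
#' frame's displacement trace, and accumulated into a per-pixel
#' micro-time histogram. Each kept photon contributes exactly one count.
#' Photons landing outside the image are dropped and counted, as are
#' photons of frames whose correlation fell below `r_thresh` and photons
#' never assigned to a pixel (pre-scan or retrace intervals).
#'
#' @param stream A [tttr_stream()].
#' @param traces Per-frame [displacement_trace()] list (a single trace is
#'   recycled across frames).
#' @param geom A [scan_geometry()].
#' @param r_values Per-frame correlation values (needed with `r_thresh`).
#' @param r_thresh Correlation threshold; frames with `r < r_thresh` are
#'   excluded from the reconstruction.
#' @param n_t Number of micro-time bins in the output histogram (micro
#'   times are rebinned by an integer factor; default: the native bin
#'   count `rep_period / micro_resolution`).
#' @return Object of class `flim_image`: `histogram`
#'   (`[n_y, n_x, n_z, n_channels, n_t]` counts), `integration_time`
#'   (`[n_y, n_x, n_z]` effective dwell, macro ticks),
#'   `excluded_frames` (0-based), `r_thresh`, `counts` (photon
#'   accounting: input, unassigned, excluded, out_of_bounds, kept),
#'   `geometry`, `n_t`.
#' @export
reassign_photons <- function(stream, traces, geom, r_values = NULL,
                             r_thresh = NULL, n_t = NULL) {
  nf <- n_frames(stream)
  traces <- check_traces(traces, nf)
  keep_frames <- frames_to_keep(nf, r_values, r_thresh)
  native_nt <- max(1L, round(geom$rep_period / geom$micro_resolution))
  if (is.null(n_t)) n_t <- native_nt
  rebin <- max(1L, floor(native_nt / n_t))

  px <- assign_pixels(stream, geom)
  ph <- stream$photons
  n_input <- nrow(ph)
  ok <- px$assigned & px$frame < nf
  n_unassigned <- sum(!ok)
  in_kept <- ok & (px$frame + 1L) %in% keep_frames
  n_excluded <- sum(ok) - sum(in_kept)

  idx <- which(in_kept)
  xs <- px$x[idx]; ys <- px$y[idx]; zs <- px$z[idx]
  fr <- px$frame[idx]; tr <- px$t_rel[idx]
  Dx <- numeric(length(idx)); Dy <- numeric(length(idx))
  Dz <- numeric(length(idx))
  for (f in unique(fr)) {
    sel <- fr == f
    D <- displacement_at(traces[[f + 1L]], tr[sel])
    Dx[sel] <- D[, 1]; Dy[sel] <- D[, 2]
    if (ncol(D) == 3) Dz[sel] <- D[, 3]
  }
  nx <- round_half_up(xs - Dx)
  ny <- round_half_up(ys - Dy)
  nz <- round_half_up(zs - Dz)
  inb <- nx >= 0 & nx < geom$n_x & ny >= 0 & ny < geom$n_y &
         nz >= 0 & nz < geom$n_z
  n_oob <- sum(!inb)

  ch <- pmin(pmax(ph$channel[idx][inb], 0L), geom$n_channels - 1L)
  tb <- pmin(ph$micro_time[idx][inb] %/% rebin, n_t - 1L)
  nvox <- geom$n_y * geom$n_x * geom$n_z
  lin <- ((tb * geom$n_channels + ch) * geom$n_z + nz[inb]) *
    (geom$n_y * geom$n_x) + nx[inb] * geom$n_y + ny[inb] + 1
  counts <- tabulate(lin, nbins = nvox * geom$n_channels * n_t)
  hist <- array(counts,
                dim = c(geom$n_y, geom$n_x, geom$n_z, geom$n_channels, n_t))

  itime <- integration_time_image(traces, r_values, geom, r_thresh)
  structure(list(
    histogram = hist,
    integration_time = itime,
    excluded_frames = setdiff(seq_len(nf), keep_frames) - 1L,
    r_thresh = r_thresh,
    counts = list(input = n_input, unassigned = n_unassigned,
                  excluded = n_excluded, out_of_bounds = n_oob,
                  kept = sum(inb)),
    geometry = geom, n_t = n_t
  ), class = "flim_image")
}

#' @export
print.flim_image <- function(x, ...) {
  d <- dim(x$histogram)
  cat(sprintf("flim_image: %d x %d x %d, %d channel(s), %d time bins\n",
              d[2], d[1], d[3], d[4], d[5]))
  cat(sprintf("  photons kept %d / %d (unassigned %d, excluded %d, oob %d)\n",
              x$counts$kept, x$counts$input, x$counts$unassigned,
              x$counts$excluded, x$counts$out_of_bounds))
  if (length(x$excluded_frames)) {
    cat("  excluded frames:", paste(x$excluded_frames, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Effective integration-time image after reassignment
#'
#' Sample motion makes the effective dwell time vary across the corrected
#' image. For every included frame, each scan pixel's dwell `t_pixel` is
#' deposited at its reassigned location (the same rounding as photons);
#' the summed image is used to normalise intensity without altering the
#' photon statistics of the data used for analysis.
#'
#' @inheritParams reassign_photons
#' @return `[n_y, n_x, n_z]` array of accumulated dwell time (macro ticks).
#' @export
integration_time_image <- function(traces, r_values = NULL, geom,
                                   r_thresh = NULL) {
  if (inherits(traces, "displacement_trace")) traces <- list(traces)
  nf <- length(traces)
  keep_frames <- frames_to_keep(nf, r_values, r_thresh)
  tpx <- as.vector(pixel_time_array(geom))
  xs <- rep(rep(seq_len(geom$n_x) - 1, each = geom$n_y), times = geom$n_z)
  ys <- rep(seq_len(geom$n_y) - 1, times = geom$n_x * geom$n_z)
  zs <- rep(seq_len(geom$n_z) - 1, each = geom$n_x * geom$n_y)
  nvox <- geom$n_y * geom$n_x * geom$n_z
  acc <- numeric(nvox)
  for (f in keep_frames) {
    D <- displacement_at(traces[[f]], tpx)
    nx <- round_half_up(xs - D[, 1])
    ny <- round_half_up(ys - D[, 2])
    nz <- if (ncol(D) == 3) round_half_up(zs - D[, 3]) else zs
    inb <- nx >= 0 & nx < geom$n_x & ny >= 0 & ny < geom$n_y &
           nz >= 0 & nz < geom$n_z
    lin <- nz[inb] * (geom$n_y * geom$n_x) + nx[inb] * geom$n_y + ny[inb] + 1
    acc <- acc + geom$t_pixel * tabulate(lin, nbins = nvox)
  }
  array(acc, dim = c(geom$n_y, geom$n_x, geom$n_z))
}

#' Reassigned per-frame intensity images
#'
#' Builds each frame's motion-corrected intensity image by per-photon
#' reassignment under that frame's displacement trace (the
#' intensity-preserving reconstruction, frame by frame). This is the
#' image whose correlation with the reference genuinely measures
#' correction quality: unlike the estimation warp it cannot duplicate
#' lines, so unrecovered motion shows up as gaps and pile-up.
#'
#' @param stream A [tttr_stream()].
#' @param traces Per-frame [displacement_trace()] list (single trace
#'   recycled).
#' @param geom A [scan_geometry()].
#' @return List of `[n_y, n_x, n_z]` count arrays, one per frame.
#' @export
reassigned_frame_images <- function(stream, traces, geom) {
  nf <- n_frames(stream)
  traces <- check_traces(traces, nf)
  px <- assign_pixels(stream, geom)
  nvox <- geom$n_y * geom$n_x * geom$n_z
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    sel <- which(px$assigned & px$frame == f - 1L)
    D <- displacement_at(traces[[f]], px$t_rel[sel])
    nx <- round_half_up(px$x[sel] - D[, 1])
    ny <- round_half_up(px$y[sel] - D[, 2])
    nz <- if (ncol(D) == 3) round_half_up(px$z[sel] - D[, 3]) else px$z[sel]
    inb <- nx >= 0 & nx < geom$n_x & ny >= 0 & ny < geom$n_y &
           nz >= 0 & nz < geom$n_z
    lin <- nz[inb] * (geom$n_y * geom$n_x) + nx[inb] * geom$n_y + ny[inb] + 1
    out[[f]] <- array(tabulate(lin, nbins = nvox),
                      dim = c(geom$n_y, geom$n_x, geom$n_z))
  }
  out
}

#' Motion-correct a multi-channel intensity time series
#'
#' Applies fitted traces to pre-binned intensity data (e.g. time-lapse
#' multispectral stacks): every voxel's value is forward-deposited at its
#' reassigned (rounded) location, all channels sharing one trace per time
#' point, and the accumulated intensity is normalised by the accumulated
#' dwell so unevenly sampled pixels keep their mean brightness. Time
#' points excluded by the correlation threshold are passed through
#' unchanged and flagged.
#'
#' @param frames List of `[n_y, n_x, n_z]` or `[n_y, n_x, n_z, n_ch]`
#'   arrays, one per time point.
#' @param traces Per-time-point [displacement_trace()] list.
#' @param geom A [scan_geometry()].
#' @param r_values,r_thresh Optional per-time-point correlations and
#'   exclusion threshold.
#' @return list with `corrected` (list of arrays), `dwell` (list of
#'   `[n_y, n_x, n_z]` deposit counts), `excluded` (0-based indices).
#' @export
correct_intensity_series <- function(frames, traces, geom,
                                     r_values = NULL, r_thresh = NULL) {
  nf <- length(frames)
  traces <- check_traces(traces, nf)
  nch <- vapply(frames, function(f) {
    if (length(dim(f)) >= 4) dim(f)[4] else 1L
  }, numeric(1))
  if (length(unique(nch)) != 1) {
    stop("format error: channel count differs across time points")
  }
  nch <- nch[1]
  keep_frames <- frames_to_keep(nf, r_values, r_thresh)
  tpx <- as.vector(pixel_time_array(geom))
  xs <- rep(rep(seq_len(geom$n_x) - 1, each = geom$n_y), times = geom$n_z)
  ys <- rep(seq_len(geom$n_y) - 1, times = geom$n_x * geom$n_z)
  zs <- rep(seq_len(geom$n_z) - 1, each = geom$n_x * geom$n_y)
  nvox <- geom$n_y * geom$n_x * geom$n_z
  out <- vector("list", nf)
  dwell <- vector("list", nf)
  for (f in seq_len(nf)) {
    arr <- frames[[f]]
    if (length(dim(arr)) == 2) arr <- array(arr, dim = c(dim(arr), 1))
    if (!(f %in% keep_frames)) {
      out[[f]] <- arr
      dwell[[f]] <- array(1, dim = c(geom$n_y, geom$n_x, geom$n_z))
      next
    }
    D <- displacement_at(traces[[f]], tpx)
    nx <- round_half_up(xs - D[, 1])
    ny <- round_half_up(ys - D[, 2])
    nz <- if (ncol(D) == 3) round_half_up(zs - D[, 3]) else zs
    inb <- nx >= 0 & nx < geom$n_x & ny >= 0 & ny < geom$n_y &
           nz >= 0 & nz < geom$n_z
    lin <- nz[inb] * (geom$n_y * geom$n_x) + nx[inb] * geom$n_y + ny[inb] + 1
    dw <- tabulate(lin, nbins = nvox)
    corr <- array(0, dim = c(geom$n_y, geom$n_x, geom$n_z, nch))
    for (ch in seq_len(nch)) {
      vals <- if (length(dim(arr)) >= 4) arr[, , , ch] else arr
      rs <- rowsum(as.vector(vals)[inb], group = lin, reorder = FALSE)
      plane <- numeric(nvox)
      plane[as.integer(rownames(rs))] <- rs[, 1]
      plane[dw > 0] <- plane[dw > 0] / dw[dw > 0]
      corr[, , , ch] <- array(plane, dim = c(geom$n_y, geom$n_x, geom$n_z))
    }
    if (nch == 1) corr <- array(corr, dim = c(geom$n_y, geom$n_x, geom$n_z))
    out[[f]] <- corr
    dwell[[f]] <- array(dw, dim = c(geom$n_y, geom$n_x, geom$n_z))
  }
  list(corrected = out, dwell = dwell,
       excluded = setdiff(seq_len(nf), keep_frames) - 1L)
}
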
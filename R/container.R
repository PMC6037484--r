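#' Open TTTR container I/O
#'
#' `write_container()` and `read_container()` persist a photon/marker event
#' stream plus its scan geometry as a single Apache Parquet file, an open
#' columnar format readable from any language. The layout is one events
#' table sorted by macro time with columns `macro_time` (ticks),
#' `kind` (0 = photon, otherwise a [marker_kinds] code), `micro_time`
#' (bins; 0 for markers) and `channel` (0 for markers), plus file-level
#' metadata key `scan_geometry` holding the geometry attributes
#' (`n_x`, `n_y`, `n_z`, `n_channels`, timing in ticks, and
#' `macro_resolution_s`, `micro_resolution_s`, `rep_period_s`) as JSON.
#'
#' @param stream A [tttr_stream()].
#' @param geom A [scan_geometry()] (defaults to the one carried by the
#'   stream).
#' @param path File path.
#' @return `read_container()` returns a [tttr_stream()] whose `geometry`
#'   field is populated; `write_container()` returns `path` invisibly.
#' @export
write_container <- function(stream, path, geom = stream$geometry) {
  if (is.null(geom)) stop("no scan geometry supplied with the stream")
  ph <- stream$photons
  mk <- stream$markers
  ev <- data.frame(
    macro_time = c(ph$macro_time, mk$macro_time),
    kind = c(rep(0L, nrow(ph)), as.integer(mk$kind)),
    micro_time = c(as.integer(ph$micro_time), rep(0L, nrow(mk))),
    channel = c(as.integer(ph$channel), rep(0L, nrow(mk)))
  )
  # stable sort by macro time only: photon and marker sub-streams each keep
  # their original order among tied ticks, so round-trips are identical
  ord <- order(ev$macro_time, method = "radix")
  ev <- ev[ord, , drop = FALSE]
  tb <- arrow::arrow_table(ev)
  meta <- unclass(geom)
  tb$metadata$scan_geometry <- as.character(
    jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)
  )
  arrow::write_parquet(tb, path)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop("container file not found: ", path)
  tb <- arrow::read_parquet(path, as_data_frame = FALSE)
  need <- c("macro_time", "kind", "micro_time", "channel")
  if (!all(need %in% names(tb))) {
    stop("container format error: missing events columns ",
         paste(setdiff(need, names(tb)), collapse = ", "))
  }
  gj <- tb$metadata$scan_geometry
  if (is.null(gj)) {
    stop("container format error: missing scan_geometry metadata")
  }
  g <- jsonlite::fromJSON(gj)
  need_attr <- c("n_x", "n_y", "n_z", "t_line", "t_interline", "t_slice",
                 "t_frame", "n_channels", "macro_resolution",
                 "micro_resolution", "rep_period")
  miss <- setdiff(need_attr, names(g))
  if (length(miss)) {
    stop("container format error: missing geometry attribute(s) ",
         paste(miss, collapse = ", "))
  }
  geom <- scan_geometry(
    n_x = g$n_x, n_y = g$n_y, n_z = g$n_z,
    t_line = g$t_line, t_interline = g$t_interline,
    t_slice = g$t_slice, t_frame = g$t_frame,
    n_channels = g$n_channels,
    macro_resolution = g$macro_resolution,
    micro_resolution = g$micro_resolution,
    rep_period = g$rep_period
  )
  ev <- as.data.frame(tb)
  bad <- which(diff(ev$macro_time) < 0)
  if (length(bad)) {
    stop(sprintf("container data error: macro times decrease at event %d",
                 bad[1] + 1L))
  }
  is_ph <- ev$kind == 0L
  tttr_stream(
    photons = data.frame(macro_time = ev$macro_time[is_ph],
                         micro_time = ev$micro_time[is_ph],
                         channel = ev$channel[is_ph]),
    markers = data.frame(macro_time = ev$macro_time[!is_ph],
                         kind = ev$kind[!is_ph]),
    geometry = geom
  )
}
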
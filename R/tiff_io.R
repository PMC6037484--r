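#' Write / read a multi-channel intensity time series as TIFF
#'
#' Intensity series are exchanged as multi-page 32-bit float TIFF with
#' pages in TCZYX nesting order (time slowest), plus a sidecar XML
#' companion (`<path>.meta.xml`) recording the axis order, the dimension
#' sizes and the intensity scale (pages are stored divided by the global
#' maximum). The reader accepts any axis order declared in the companion
#' and permutes back.
#'
#' @param frames List of `[n_y, n_x, n_z]` or `[n_y, n_x, n_z, n_ch]`
#'   arrays, one per time point.
#' @param path Output TIFF path.
#' @return `write_intensity_series()` returns `path` invisibly;
#'   `read_intensity_series()` returns the list of arrays
#'   (`[n_y, n_x, n_z, n_ch]`).
#' @export
write_intensity_series <- function(frames, path) {
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 2) f <- array(f, dim = c(dim(f), 1))
    if (length(dim(f)) == 3) f <- array(f, dim = c(dim(f), 1))
    f
  })
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1)))) {
    stop("all time points must share one shape")
  }
  scale <- max(1e-12, max(vapply(frames, max, numeric(1))))
  pages <- list()
  for (ti in seq_along(frames)) {
    for (ci in seq_len(d[4])) {
      for (zi in seq_len(d[3])) {
        pages[[length(pages) + 1]] <- frames[[ti]][, , zi, ci] / scale
      }
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  doc <- xml2::xml_new_root("IntensitySeries")
  xml2::xml_set_attrs(doc, c(
    axes = "TCZYX", size_t = length(frames), size_c = d[4], size_z = d[3],
    size_y = d[1], size_x = d[2], scale = format(scale, digits = 17)
  ))
  xml2::write_xml(doc, paste0(path, ".meta.xml"))
  invisible(path)
}

#' @rdname write_intensity_series
#' @export
read_intensity_series <- function(path) {
  meta_path <- paste0(path, ".meta.xml")
  if (!file.exists(meta_path)) stop("missing metadata companion: ", meta_path)
  doc <- xml2::read_xml(meta_path)
  at <- function(nm) xml2::xml_attr(doc, nm)
  axes <- at("axes")
  sizes <- c(T = as.integer(at("size_t")), C = as.integer(at("size_c")),
             Z = as.integer(at("size_z")), Y = as.integer(at("size_y")),
             X = as.integer(at("size_x")))
  scale <- as.numeric(at("scale"))
  pages <- tiff::readTIFF(path, all = TRUE)
  page_axes <- setdiff(strsplit(axes, "")[[1]], c("Y", "X"))
  if (!setequal(page_axes, c("T", "C", "Z"))) {
    stop("unsupported axis order: ", axes)
  }
  np <- sizes["T"] * sizes["C"] * sizes["Z"]
  if (length(pages) != np) stop("page count does not match metadata")
  # page index -> (t, c, z): first declared axis varies slowest
  strides <- rev(cumprod(rev(c(sizes[page_axes][-1], 1))))
  names(strides) <- page_axes
  out <- lapply(seq_len(sizes["T"]), function(i) {
    array(0, dim = unname(sizes[c("Y", "X", "Z", "C")]))
  })
  for (p in seq_len(np)) {
    rem <- p - 1L
    coord <- integer(3); names(coord) <- page_axes
    for (ax in page_axes) {
      coord[ax] <- rem %/% strides[ax]
      rem <- rem %% strides[ax]
    }
    out[[coord["T"] + 1L]][, , coord["Z"] + 1L, coord["C"] + 1L] <-
      pages[[p]] * scale
  }
  out
}
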
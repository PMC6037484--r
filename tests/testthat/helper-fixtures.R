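# Shared fixtures: tiny geometries, smooth scenes and hand-built streams.

tiny_geometry <- function(n_x = 16L, n_y = 16L, n_z = 1L, line_rate = 1000) {
  default_scan_geometry(n_x = n_x, n_y = n_y, line_rate = line_rate)
}

geometry_3d <- function(n_x = 16L, n_y = 16L, n_z = 4L) {
  scan_geometry(n_x = n_x, n_y = n_y, n_z = n_z,
                t_line = 160, t_interline = 40)
}

# Very smooth scene (wide Gaussians) for gradient-based oracles.
smooth_scene <- function(n = 64L, seed = 11L) {
  set.seed(seed)
  xs <- seq_len(n)
  img <- matrix(0.1, n, n)
  for (i in 1:6) {
    cx <- runif(1, 0.25 * n, 0.75 * n)
    cy <- runif(1, 0.25 * n, 0.75 * n)
    sg <- runif(1, n / 8, n / 5)
    img <- img + runif(1, 0.4, 1) *
      outer(exp(-0.5 * ((xs - cy) / sg)^2), exp(-0.5 * ((xs - cx) / sg)^2))
  }
  array(img / max(img), dim = c(n, n, 1))
}

smooth_scene_3d <- function(n = 16L, n_z = 4L, seed = 5L) {
  set.seed(seed)
  arr <- array(0.1, dim = c(n, n, n_z))
  xs <- seq_len(n)
  for (z in seq_len(n_z)) {
    for (i in 1:3) {
      cx <- runif(1, 4, n - 4); cy <- runif(1, 4, n - 4)
      sg <- runif(1, 2.5, 5)
      arr[, , z] <- arr[, , z] + runif(1, 0.4, 1) *
        outer(exp(-0.5 * ((xs - cy) / sg)^2), exp(-0.5 * ((xs - cx) / sg)^2))
    }
  }
  arr / max(arr)
}

# Markers for `nf` ideal frames of a given geometry (no jitter).
ideal_markers <- function(geom, nf) {
  s2s <- geom$t_line + geom$t_interline
  mt <- c(); kd <- c()
  for (f in seq_len(nf)) {
    t0 <- (f - 1) * geom$t_frame
    ls <- t0 + (seq_len(geom$n_y * geom$n_z) - 1) * s2s
    mt <- c(mt, t0, as.vector(rbind(ls, ls + geom$t_line)))
    kd <- c(kd, MARKER_FRAME_START,
            rep(c(MARKER_LINE_START, MARKER_LINE_END), geom$n_y * geom$n_z))
  }
  data.frame(macro_time = mt, kind = as.integer(kd))
}

empty_photons <- function() {
  data.frame(macro_time = numeric(0), micro_time = integer(0),
             channel = integer(0))
}

# Small default simulated stream used across tests.
sim_small_stream <- function(n = 16L, n_frames = 3L, seed = 99L, A = 0,
                             f = 0, theta = 0) {
  geom <- tiny_geometry(n, n)
  img <- make_test_image(n, n, seed = 7L)
  stream <- simulate_tttr(img, motion_spec(A, f, theta), emission_spec(),
                          geom, n_frames = n_frames, seed = seed)
  list(stream = stream, geom = geom, img = img)
}
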
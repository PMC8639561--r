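# fixtures are generated in code; no image files ship with the package

rand_series <- function(N, H, W, seed, scale = 65535, dt = 0.04,
                        pixel_size = 1e-6) {
  set.seed(seed)
  image_series(array(runif(N * H * W) * scale, c(N, H, W)),
               dt = dt, pixel_size = pixel_size)
}

# max deviation relative to the overall scale of the reference array
rel_max_dev <- function(ref, x) {
  s <- max(abs(ref))
  if (s == 0) return(max(abs(x)))
  max(abs(ref - x)) / s
}

# full-plane wave-vector magnitudes by exhaustive enumeration (oracle used
# against the half-plane grid and the ring binning)
full_plane_qmag <- function(H, W, pixel_size) {
  ky <- c(0:(H / 2 - 1), -(H / 2):-1)
  kx <- c(0:(W / 2 - 1), -(W / 2):-1)
  qy <- 2 * pi * ky / (H * pixel_size)
  qx <- 2 * pi * kx / (W * pixel_size)
  sqrt(outer(qy^2, qx^2, "+"))
}

make_radial <- function(q, dmat, lags, dt) {
  structure(list(q_centers = q, d_radial = dmat,
                 ring_counts = rep(1L, length(q)), lags = lags, dt = dt,
                 algorithm = "synthetic", dq = if (length(q) > 1) diff(q)[1] else q),
            class = "radial_structure")
}
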
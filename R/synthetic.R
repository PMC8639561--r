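#' Configuration for a synthetic Brownian-motion image series
#'
#' Defaults emulate a desk-scale acquisition: 25 Hz framing (`dt = 0.04` s),
#' 128 x 128 frames of 1 um pixels, 200 particles with `D = 0.5 um^2/s`,
#' imaged as Gaussian blobs of 2 px width on a constant background with
#' additive Gaussian camera noise. Gaussian blobs keep the signal
#' band-limited, so the wave-number band carrying signal (and hence the band
#' where decay times are recoverable) is predictable: spectral power dies off
#' beyond roughly `1/blob_sigma` in inverse-pixel units.
#'
#' @param n_particles number of particles.
#' @param D_true diffusion coefficient, m^2/s.
#' @param N number of frames.
#' @param H,W frame size in pixels (even).
#' @param dt frame interval, s.
#' @param pixel_size pixel side, m.
#' @param blob_sigma Gaussian particle-image width, pixels (`>= 1`).
#' @param intensity peak counts per particle.
#' @param background constant background counts.
#' @param noise_sigma additive Gaussian camera-noise standard deviation,
#'   counts.
#' @param seed mandatory integer seed (R's Mersenne-Twister; the generator is
#'   fully reproducible from it).
#' @return A `brownian_config` list.
#' @export
brownian_config <- function(n_particles = 200L, D_true = 0.5e-12, N = 1024L,
                            H = 128L, W = 128L, dt = 0.04, pixel_size = 1e-6,
                            blob_sigma = 2, intensity = 1000, background = 100,
                            noise_sigma = 5, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  cfg <- list(n_particles = as.integer(n_particles), D_true = D_true,
              N = as.integer(N), H = as.integer(H), W = as.integer(W),
              dt = dt, pixel_size = pixel_size, blob_sigma = blob_sigma,
              intensity = intensity, background = background,
              noise_sigma = noise_sigma, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_particles >= 1, D_true >= 0, N >= 2, H >= 2, W >= 2,
              dt > 0, pixel_size > 0, intensity > 0, background >= 0,
              noise_sigma >= 0)
    if (blob_sigma < 1)
      stop("blob_sigma must be >= 1 pixel (narrower blobs alias badly)",
           call. = FALSE)
    if (6 * blob_sigma >= min(H, W))
      stop("blobs larger than the frame: shrink blob_sigma or enlarge frame",
           call. = FALSE)
  })
  structure(cfg, class = "brownian_config")
}

#' Generate a Brownian-motion image series with known dynamics
#'
#' Particles start uniformly at random and advance each frame by independent
#' Gaussian steps of per-axis variance `2 * D_true * dt` (converted to
#' pixels), wrapping periodically at the frame edges. Each frame renders the
#' particles as Gaussian blobs of peak `intensity` on the constant
#' `background`, plus i.i.d. Gaussian camera noise. The resulting
#' intermediate scattering function is `exp(-D_true * q^2 * t)` in the
#' wave-number band where the blobs carry signal, making the whole analysis
#' chain verifiable against a known diffusion coefficient.
#'
#' The latent unwrapped trajectories (in pixels) are attached as
#' `attr(series, "trajectories")` (`N x n_particles x 2` array, x then y), so
#' displacement-level checks need not re-infer positions from images.
#'
#' @param cfg a [brownian_config()].
#' @return An [image_series] with attributes `trajectories` and `config`.
#' @export
generate_brownian_series <- function(cfg) {
  stopifnot(inherits(cfg, "brownian_config"))
  set.seed(cfg$seed)
  P <- cfg$n_particles
  N <- cfg$N; H <- cfg$H; W <- cfg$W
  step_sd <- sqrt(2 * cfg$D_true * cfg$dt) / cfg$pixel_size  # pixels
  x <- runif(P) * W
  y <- runif(P) * H
  traj <- array(0, c(N, P, 2L))
  traj[1, , 1] <- x; traj[1, , 2] <- y
  if (N > 1) {
    traj[, , 1] <- apply(rbind(x, matrix(rnorm((N - 1) * P, 0, step_sd),
                                         N - 1, P)), 2, cumsum)
    traj[, , 2] <- apply(rbind(y, matrix(rnorm((N - 1) * P, 0, step_sd),
                                         N - 1, P)), 2, cumsum)
  }
  frames <- array(0, c(N, H, W))
  Rr <- ceiling(4 * cfg$blob_sigma)
  off <- (-Rr):Rr
  L <- length(off)
  iy_rep <- rep(seq_len(L), times = L)   # (dy, dx) combos, dy fastest
  ix_rep <- rep(seq_len(L), each = L)
  for (n in seq_len(N)) {
    px <- traj[n, , 1] %% W
    py <- traj[n, , 2] %% H
    ax <- floor(px); ay <- floor(py)
    # separable Gaussian stamp weights, L x P
    wx <- exp(-(outer(off, ax - px, "+"))^2 / (2 * cfg$blob_sigma^2))
    wy <- exp(-(outer(off, ay - py, "+"))^2 / (2 * cfg$blob_sigma^2))
    colx <- (outer(off, ax, "+")) %% W     # 0-based column index, L x P
    rowy <- (outer(off, ay, "+")) %% H
    vals <- cfg$intensity * wy[iy_rep, , drop = FALSE] *
      wx[ix_rep, , drop = FALSE]
    idx <- rowy[iy_rep, , drop = FALSE] + H * colx[ix_rep, , drop = FALSE]
    acc <- rowsum(as.vector(vals), as.vector(idx))
    frame <- matrix(cfg$background, H, W)
    frame[as.integer(rownames(acc)) + 1L] <- cfg$background + acc
    if (cfg$noise_sigma > 0)
      frame <- frame + rnorm(H * W, 0, cfg$noise_sigma)
    frames[n, , ] <- frame
  }
  series <- image_series(frames, dt = cfg$dt, pixel_size = cfg$pixel_size)
  attr(series, "trajectories") <- traj
  attr(series, "config") <- cfg
  series
}

#' Generate an i.i.d. Gaussian noise image series
#'
#' Zero-mean white noise frames of standard deviation `sigma`. Because frames
#' are mutually independent, the expected structure function is flat:
#' `E d(m, q) = 2 * H * W * sigma^2` for every lag `m >= 1` and `q != 0`
#' under the unnormalized FFT convention — the analytic noise plateau used to
#' validate the engines' normalization.
#'
#' @param N number of frames (`>= 2`).
#' @param H,W frame size in pixels.
#' @param sigma noise standard deviation, counts.
#' @param seed integer seed.
#' @return An [image_series] (`dt = 1` s, `pixel_size = 1` m by convention —
#'   the plateau does not depend on them).
#' @export
generate_noise_series <- function(N, H, W, sigma, seed) {
  stopifnot(N >= 2, sigma > 0)
  set.seed(seed)
  frames <- array(rnorm(N * H * W, 0, sigma), c(N, H, W))
  image_series(frames, dt = 1, pixel_size = 1)
}
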
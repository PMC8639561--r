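#' Wave-vector geometry of the Hermitian-reduced half plane
#'
#' A real image's 2D Fourier transform satisfies conjugate symmetry, so only
#' the half plane of column frequencies `kx = 0..W/2` need be stored. Columns
#' `0 < kx < W/2` stand for two full-plane wave vectors each; the `kx = 0` and
#' Nyquist columns are self-conjugate. The multiplicity array records this so
#' half-plane averages reproduce full-plane averages exactly.
#'
#' Wave-vector components are `q_i = 2*pi*k_i / (n_i * pixel_size)` in rad/m,
#' with integer frequency index `k_i` in `[-n_i/2, n_i/2)`.
#'
#' @param H,W frame dimensions; both must be even (odd sizes are rejected to
#'   keep Nyquist handling unambiguous).
#' @param pixel_size pixel side in meters.
#' @return An object of class `wavevector_grid`: list with `H`, `W`,
#'   `pixel_size`, `q_magnitudes` (`H x (W/2+1)` matrix, rad/m) and
#'   `multiplicity` (same shape, integers summing to `H*W`).
#' @examples
#' g <- wavevector_grid(4, 4, 1)
#' g$q_magnitudes[1, 2]  # 2*pi/4
#' @export
wavevector_grid <- function(H, W, pixel_size) {
  stopifnot(H > 0, W > 0, pixel_size > 0)
  if (H %% 2L != 0L || W %% 2L != 0L)
    stop("frame dimensions must be even, got ", H, " x ", W, call. = FALSE)
  ky <- c(0:(H / 2 - 1), -(H / 2):-1)          # fft row-frequency order
  kx <- 0:(W / 2)
  qy <- 2 * pi * ky / (H * pixel_size)
  qx <- 2 * pi * kx / (W * pixel_size)
  qmag <- sqrt(outer(qy^2, qx^2, "+"))
  mult <- matrix(2L, H, W / 2 + 1)
  mult[, c(1L, W / 2 + 1L)] <- 1L
  structure(
    list(H = as.integer(H), W = as.integer(W), pixel_size = pixel_size,
         q_magnitudes = qmag, multiplicity = mult),
    class = "wavevector_grid"
  )
}

#' @export
print.wavevector_grid <- function(x, ...) {
  cat(sprintf("<wavevector_grid> %d x %d px, pixel = %g m, dq = %g rad/m\n",
              x$H, x$W, x$pixel_size,
              2 * pi / (max(x$H, x$W) * x$pixel_size)))
  invisible(x)
}

#' Spatial Fourier transforms of every frame
#'
#' Step one of both structure-function algorithms: the unnormalized forward 2D
#' FFT of each frame, stored on the Hermitian-reduced half plane. Caching these
#' spectra is what lets the accelerated engines reuse each transform across all
#' time lags instead of transforming every frame pair.
#'
#' No window or apodization is applied, and no 1/(H*W) factor: the DC entry of
#' frame `n` equals the sum of its pixels, and Parseval's identity reads
#' `sum_fullplane |Ihat|^2 = H*W * sum_xy I^2`.
#'
#' @param series an [image_series].
#' @return An object of class `spectrum_stack`: list with `spectra` (complex
#'   `N x H x (W/2+1)` array), `grid` (a [wavevector_grid]) and `dt`.
#' @export
spatial_fft <- function(series) {
  stopifnot(inherits(series, "image_series"))
  fr <- series$frames
  if (!all(is.finite(fr)))
    stop("frames contain non-finite pixel values", call. = FALSE)
  d <- dim(fr)
  N <- d[1]; H <- d[2]; W <- d[3]
  grid <- wavevector_grid(H, W, series$pixel_size)
  W2 <- W / 2 + 1
  spectra <- array(0i, c(N, H, W2))
  for (n in seq_len(N)) {
    spectra[n, , ] <- stats::fft(fr[n, , ])[, seq_len(W2)]
  }
  structure(list(spectra = spectra, grid = grid, dt = series$dt),
            class = "spectrum_stack")
}

#' @export
print.spectrum_stack <- function(x, ...) {
  d <- dim(x$spectra)
  cat(sprintf("<spectrum_stack> %d half-plane spectra of %d x %d, dt = %g s\n",
              d[1], d[2], d[3], x$dt))
  invisible(x)
}

# Rebuild the full H x W complex plane from a half-plane matrix by conjugate
# symmetry; used by tests and the azimuthal-average cross-checks.
hermitian_full_plane <- function(half, H, W) {
  full <- matrix(0i, H, W)
  W2 <- W / 2 + 1
  full[, seq_len(W2)] <- half
  for (kx in seq_len(W / 2 - 1)) {         # columns W/2+2 .. W  <-  conj fold
    src <- half[, kx + 1L]
    full[, W - kx + 1L] <- Conj(src[c(1L, H:2L)])
  }
  full
}
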
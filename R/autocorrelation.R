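#' Linear lagged autocorrelation via the temporal FFT
#'
#' Computes `C(m) = sum_{n=m}^{N-1} conj(ts[n-m]) * ts[n]` for `m = 0..N-1`
#' (0-based lags) by the Wiener-Khinchin route: zero-pad the series to the
#' smallest power of two `P >= 2N`, take the forward transform, form the
#' squared modulus, inverse transform, and read lags `0..N-1`. The padding
#' makes the circular correlation of the FFT identical to the linear finite
#' sum, so the identity above holds exactly (up to rounding); without it the
#' large lags would wrap around and contaminate small ones.
#'
#' This is the O(N log N) kernel that replaces the O(N^2) pairwise pass over a
#' wave vector's time series.
#'
#' @param ts complex (or numeric) vector of length `N >= 1`.
#' @return Complex vector of length `N`, `C(m)` at lags `0..N-1`.
#' @examples
#' ts <- complex(real = rnorm(8), imaginary = rnorm(8))
#' C <- lagged_autocorrelation(ts)
#' all.equal(Re(C[1]), sum(Mod(ts)^2))
#' @export
lagged_autocorrelation <- function(ts) {
  if (length(ts) < 1L) stop("empty time series", call. = FALSE)
  N <- length(ts)
  P <- next_pow2(2L * N)
  a <- c(as.complex(ts), rep(0i, P - N))
  A <- stats::fft(a)
  C <- stats::fft(Mod(A)^2 + 0i, inverse = TRUE) / P
  C[seq_len(N)]
}

next_pow2 <- function(n) {
  p <- 1L
  while (p < n) p <- p * 2L
  p
}
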
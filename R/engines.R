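new_structure_function <- function(d, lags, N, dt, grid, algorithm, work) {
  structure(
    list(d = d, lags = as.integer(lags), pair_counts = N - as.integer(lags),
         n_frames = as.integer(N), dt = dt, grid = grid,
         algorithm = algorithm, work = work),
    class = "structure_function"
  )
}

#' @export
print.structure_function <- function(x, ...) {
  cat(sprintf(
    "<structure_function> engine '%s': %d lags on a %d x %d half-plane grid (N = %d, dt = %g s)\n",
    x$algorithm, length(x$lags), x$grid$H, x$grid$W / 2 + 1, x$n_frames, x$dt))
  invisible(x)
}

check_lags <- function(lags, N) {
  lags <- as.integer(lags)
  if (length(lags) == 0L) stop("empty lag list", call. = FALSE)
  if (any(lags < 0L) || any(lags > N - 1L))
    stop("lags must lie in [0, N-1] = [0, ", N - 1L, "]", call. = FALSE)
  if (anyDuplicated(lags)) stop("duplicate lags", call. = FALSE)
  sort(lags)
}

#' Structure function by the literal pairwise definition
#'
#' The reference engine: for each lag `m` it forms every frame difference
#' `I[n-m] - I[n]`, transforms the difference, and averages the power spectra,
#'
#'   `d(m) = 1/(N-m) * sum_{n=m}^{N-1} | FFT2(I[n-m] - I[n]) |^2`.
#'
#' This is O(sum over lags of (N-m)) spatial FFTs — quadratic in N when all
#' lags are requested — and exists as the independent oracle against which the
#' accelerated engines are validated.
#'
#' @param series an [image_series].
#' @param lags integer lags in `[0, N-1]` (0-based); default all.
#' @return A `structure_function`: list with `d` (`|lags| x H x (W/2+1)`
#'   array), `lags`, `pair_counts` (`N - m`), `n_frames`, `dt`, `grid`,
#'   `algorithm = "naive"` and a `work` counter list.
#' @export
structure_naive <- function(series, lags = NULL) {
  stopifnot(inherits(series, "image_series"))
  fr <- series$frames
  N <- dim(fr)[1]; H <- dim(fr)[2]; W <- dim(fr)[3]
  if (is.null(lags)) lags <- 0:(N - 1)
  lags <- check_lags(lags, N)
  grid <- wavevector_grid(H, W, series$pixel_size)
  W2 <- W / 2 + 1
  d <- array(0, c(length(lags), H, W2))
  n_ffts <- 0L
  for (i in seq_along(lags)) {
    m <- lags[i]
    if (m == 0L) next  # I[n] - I[n] is identically zero
    acc <- matrix(0, H, W2)
    for (n0 in m:(N - 1L)) {
      diff <- fr[n0 - m + 1L, , ] - fr[n0 + 1L, , ]
      acc <- acc + Mod(stats::fft(diff)[, seq_len(W2)])^2
      n_ffts <- n_ffts + 1L
    }
    d[i, , ] <- acc / (N - m)
  }
  new_structure_function(d, lags, N, series$dt, grid, "naive",
                         list(spatial_ffts = n_ffts, temporal_ffts = 0L,
                              elementwise_passes = n_ffts, groups = 1L))
}

# --- engine cores on a flattened N x nq complex matrix ----------------------
# Both accelerated engines work per wave vector on the time series s(n) of one
# half-plane entry; flattening (H, W/2+1) column-major lets groups be
# contiguous column ranges.

core_direct <- function(S, lags, N) {
  d <- matrix(0, length(lags), ncol(S))
  passes <- 0L
  for (i in seq_along(lags)) {
    m <- lags[i]
    if (m == 0L) next
    idx_a <- seq_len(N - m)
    idx_b <- idx_a + m
    diff2 <- Mod(S[idx_a, , drop = FALSE] - S[idx_b, , drop = FALSE])^2
    d[i, ] <- colSums(diff2) / (N - m)
    passes <- passes + (N - m)
  }
  list(d = d, passes = passes, temporal_ffts = 0L)
}

core_wk <- function(S, lags, N) {
  nq <- ncol(S)
  P <- next_pow2(2L * N)
  # power time series and its forward/backward partial sums, O(N) per q
  p <- Mod(S)^2
  cs <- apply(p, 2L, cumsum)
  if (nq == 1L) cs <- matrix(cs, ncol = 1L)
  total <- cs[N, ]
  # lag correlation of the complex spectra via the temporal FFT
  pad <- rbind(S, matrix(0i, P - N, nq))
  Fm <- stats::mvfft(pad)
  pw <- Mod(Fm)^2
  Cm <- stats::mvfft(matrix(as.complex(pw), P, nq), inverse = TRUE) / P
  ReC <- Re(Cm[seq_len(N), , drop = FALSE])
  d <- matrix(0, length(lags), nq)
  for (i in seq_along(lags)) {
    m <- lags[i]
    if (m == 0L) next  # exact identity: the m = 0 difference vanishes
    term_first <- cs[N - m, ]          # sum of the first N-m power spectra
    term_last  <- total - cs[m, ]      # sum of the last  N-m power spectra
    d[i, ] <- (term_first + term_last - 2 * ReC[m + 1L, ]) / (N - m)
  }
  list(d = d, passes = 0L, temporal_ffts = 2L * nq)
}

flatten_spectra <- function(spectra) {
  dm <- dim(spectra)
  matrix(spectra, nrow = dm[1])          # column-major over (H, W/2+1)
}

assemble_sf <- function(dmat, lags, N, dt, grid, algorithm, work) {
  H <- grid$H; W2 <- grid$W / 2 + 1
  d <- array(dmat, c(length(lags), H, W2))
  new_structure_function(d, lags, N, dt, grid, algorithm, work)
}

#' Structure function from cached spectra (difference-in-Fourier-space engine)
#'
#' Exploits FFT linearity: `FFT2(I[n-m] - I[n]) = Ihat[n-m] - Ihat[n]`, so
#' after one spatial transform per frame each lag is an elementwise pass over
#' spectrum differences. O(N) spatial FFTs, but still O(N^2) elementwise work
#' over all lags.
#'
#' @param spectra a [spatial_fft()] result.
#' @param lags integer lags in `[0, N-1]`; default all.
#' @return A `structure_function` with `algorithm = "direct"`.
#' @export
structure_direct <- function(spectra, lags = NULL) {
  stopifnot(inherits(spectra, "spectrum_stack"))
  N <- dim(spectra$spectra)[1]
  if (is.null(lags)) lags <- 0:(N - 1)
  lags <- check_lags(lags, N)
  S <- flatten_spectra(spectra$spectra)
  res <- core_direct(S, lags, N)
  assemble_sf(res$d, lags, N, spectra$dt, spectra$grid, "direct",
              list(spatial_ffts = 0L, temporal_ffts = 0L,
                   elementwise_passes = res$passes, groups = 1L))
}

#' Structure function by the Wiener-Khinchin temporal-FFT engine
#'
#' Expands the squared modulus of the spectrum difference into two partial
#' sums of power spectra plus a cross term,
#'
#'   `d(m,q) = 1/(N-m) * [ sum_{k<=N-1-m} p(k) + sum_{n>=m} p(n) - 2 Re C(m) ]`
#'
#' with `p(n) = |Ihat_n(q)|^2`. The partial sums are cumulative sums (O(N) per
#' wave vector) and the lag correlation `C(m)` of the complex series comes
#' from [lagged_autocorrelation()]'s zero-padded temporal FFT, so the
#' per-wave-vector cost drops from O(N^2) to O(N log N). Exactly two temporal
#' transforms (forward + inverse) are spent per wave vector per memory group,
#' independent of how many lags are requested.
#'
#' @param spectra a [spatial_fft()] result.
#' @param lags integer lags in `[0, N-1]`; default all (the engine's cost does
#'   not depend on the lag count).
#' @param plan optional [plan_memory()] result; wave vectors are processed
#'   group by group in the plan's contiguous ranges. Default: single group.
#' @return A `structure_function` with `algorithm = "wk"`.
#' @export
structure_wk <- function(spectra, lags = NULL, plan = NULL) {
  stopifnot(inherits(spectra, "spectrum_stack"))
  N <- dim(spectra$spectra)[1]
  if (is.null(lags)) lags <- 0:(N - 1)
  lags <- check_lags(lags, N)
  S <- flatten_spectra(spectra$spectra)
  nq <- ncol(S)
  if (is.null(plan)) {
    ranges <- list(seq_len(nq))
  } else {
    check_plan(plan, nq)
    ranges <- plan$group_ranges
  }
  dmat <- matrix(0, length(lags), nq)
  tffts <- 0L
  for (rg in ranges) {
    res <- core_wk(S[, rg, drop = FALSE], lags, N)
    dmat[, rg] <- res$d
    tffts <- tffts + res$temporal_ffts
  }
  assemble_sf(dmat, lags, N, spectra$dt, spectra$grid, "wk",
              list(spatial_ffts = 0L, temporal_ffts = tffts,
                   elementwise_passes = 0L, groups = length(ranges)))
}

check_plan <- function(plan, nq) {
  stopifnot(inherits(plan, "memory_plan"))
  covered <- sort(unlist(plan$group_ranges))
  if (!identical(covered, seq_len(nq)))
    stop("memory plan does not partition the ", nq, " half-plane wave vectors",
         call. = FALSE)
  invisible(plan)
}
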
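#' Compute a structure function with engine selection and memory budgeting
#'
#' High-level orchestrator: picks the engine, plans the memory split, and —
#' when the budget forces more than one group — recomputes the spatial FFTs
#' for each group rather than spilling cached spectra to disk, keeping only
#' the group's half-plane columns in memory. The naive engine never caches
#' spectra and ignores the budget.
#'
#' @param series an [image_series].
#' @param algorithm `"wk"` (Wiener-Khinchin temporal FFT, default), `"direct"`
#'   (difference of cached spectra) or `"naive"` (difference of frames,
#'   reference).
#' @param lags integer lags, default all of `0..N-1`. The `"direct"` engine's
#'   cost scales with the lag count, so a sparse set (see [lag_spec()]) pays
#'   off there; the `"wk"` engine's cost does not depend on it.
#' @param budget_bytes memory budget for cached spectra, default 1 GiB.
#' @param n_groups optional explicit group count (overrides the budget).
#' @return A `structure_function`; its `work` counters record spatial FFTs,
#'   temporal FFTs, elementwise passes and the group count `G`.
#' @examples
#' s <- generate_noise_series(N = 8, H = 8, W = 8, sigma = 1, seed = 1)
#' sf <- structure_function(s, algorithm = "wk")
#' sf$work$temporal_ffts  # 2 per wave vector per group
#' @export
structure_function <- function(series,
                               algorithm = c("wk", "direct", "naive"),
                               lags = NULL, budget_bytes = 2^30,
                               n_groups = NULL) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(series, "image_series"))
  d <- dim(series$frames)
  N <- d[1]; H <- d[2]; W <- d[3]
  if (is.null(lags)) lags <- 0:(N - 1)
  lags <- check_lags(lags, N)
  if (algorithm == "naive") return(structure_naive(series, lags))

  plan <- plan_memory(N, H, W, budget_bytes = budget_bytes,
                      n_groups = n_groups)
  grid <- wavevector_grid(H, W, series$pixel_size)
  W2 <- W / 2 + 1
  nq <- H * W2
  core <- if (algorithm == "wk") core_wk else core_direct
  dmat <- matrix(0, length(lags), nq)
  spatial <- 0L; tffts <- 0L; passes <- 0L
  for (rg in plan$group_ranges) {
    # one full pass of spatial FFTs per group; only this group's wave
    # vectors are retained ("recalculating the image FFTs" trade-off)
    Sg <- matrix(0i, N, length(rg))
    for (n in seq_len(N)) {
      half <- stats::fft(series$frames[n, , ])[, seq_len(W2)]
      Sg[n, ] <- half[rg]
    }
    spatial <- spatial + N
    res <- core(Sg, lags, N)
    dmat[, rg] <- res$d
    tffts <- tffts + res$temporal_ffts
    passes <- passes + res$passes
  }
  assemble_sf(dmat, lags, N, series$dt, grid, algorithm,
              list(spatial_ffts = spatial, temporal_ffts = tffts,
                   elementwise_passes = passes, groups = plan$n_groups))
}

#' Build a lag set from a specification string
#'
#' `"all"` gives every lag `0..N-1`; `"log:K"` gives `K` unique integer lags
#' approximately log-spaced between 1 and `N-1` (both always included, gaps
#' filled with the smallest missing integers when rounding collides); a
#' comma-separated list (`"1,2,5,10"`) is taken literally.
#'
#' @param spec character specification.
#' @param N number of frames.
#' @return Sorted integer vector of lags.
#' @export
lag_spec <- function(spec, N) {
  if (identical(spec, "all")) return(0:(N - 1L))
  if (grepl("^log:[0-9]+$", spec)) {
    K <- as.integer(sub("^log:", "", spec))
    if (K < 2L || K > N - 1L)
      stop("log lag count must lie in [2, N-1]", call. = FALSE)
    lags <- unique(round(exp(seq(0, log(N - 1L), length.out = K))))
    cand <- setdiff(seq_len(N - 1L), lags)
    if (length(lags) < K) lags <- c(lags, cand[seq_len(K - length(lags))])
    return(sort(as.integer(lags)))
  }
  if (grepl("^[0-9]+(,[0-9]+)*$", spec)) {
    return(check_lags(as.integer(strsplit(spec, ",")[[1]]), N))
  }
  stop("cannot parse lag specification '", spec,
       "' (use 'all', 'log:K', or 'm1,m2,...')", call. = FALSE)
}

#' Parse a byte size with K/M/G suffix
#'
#' @param x e.g. `"512M"`, `"8G"`, `"1024"` or a plain number.
#' @return Number of bytes.
#' @export
parse_bytes <- function(x) {
  if (is.numeric(x)) return(x)
  m <- regmatches(x, regexec("^([0-9]+\\.?[0-9]*)([KMGkmg]?)$", x))[[1]]
  if (length(m) == 0L)
    stop("cannot parse byte size '", x, "'", call. = FALSE)
  suffix <- toupper(m[3])
  mult <- if (suffix == "") 1 else switch(suffix, K = 2^10, M = 2^20, G = 2^30)
  as.numeric(m[2]) * mult
}
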
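#' Plan memory-budgeted chunked execution
#'
#' When the cached per-wave-vector time series exceed the memory budget, the
#' job is split into contiguous groups of half-plane wave vectors, each
#' processed independently at the price of recomputing the spatial FFTs for
#' every group. The per-wave-vector cost is `N` complex values of the cached
#' series plus the temporal-FFT workspace of padded length `P` (smallest power
#' of two `>= 2N`), at the working precision's complex width (16 bytes double,
#' 8 bytes single).
#'
#' The group count is the minimal number of contiguous, balanced partitions
#' whose per-group cost fits the budget:
#' `G = ceil(n_wavevectors / floor(budget / bytes_per_wavevector))`.
#'
#' @param N number of frames.
#' @param H,W frame dimensions (even).
#' @param budget_bytes memory budget in bytes.
#' @param precision `"double"` (default) or `"single"`; affects the byte
#'   accounting only.
#' @param n_groups optional explicit group count overriding the budget-derived
#'   one (useful for validating chunk invariance).
#' @return An object of class `memory_plan`: list with `budget_bytes`,
#'   `n_groups`, `group_ranges` (contiguous index ranges partitioning the
#'   `H*(W/2+1)` half-plane wave vectors), `bytes_per_wavevector`.
#' @examples
#' plan_memory(N = 256, H = 64, W = 64, budget_bytes = 8 * 2^20)
#' @export
plan_memory <- function(N, H, W, budget_bytes, precision = c("double", "single"),
                        n_groups = NULL) {
  precision <- match.arg(precision)
  stopifnot(N >= 2, H %% 2 == 0, W %% 2 == 0)
  bytes_per_complex <- if (precision == "double") 16 else 8
  P <- next_pow2(2L * as.integer(N))
  bpw <- (N + P) * bytes_per_complex
  nq <- H * (W / 2 + 1)
  if (is.null(n_groups)) {
    cap <- floor(budget_bytes / bpw)
    if (cap < 1)
      stop("memory budget (", budget_bytes, " bytes) is below the cost of a ",
           "single wave vector's time series and workspace (", bpw, " bytes)",
           call. = FALSE)
    G <- as.integer(ceiling(nq / cap))
  } else {
    G <- as.integer(n_groups)
    stopifnot(G >= 1, G <= nq)
  }
  # balanced contiguous ranges: sizes differ by at most one
  sizes <- rep(nq %/% G, G)
  extra <- nq %% G
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  ranges <- Map(function(a, b) seq.int(a, b), starts, ends)
  structure(
    list(budget_bytes = budget_bytes, n_groups = G, group_ranges = ranges,
         bytes_per_wavevector = bpw, precision = precision),
    class = "memory_plan"
  )
}

#' @export
print.memory_plan <- function(x, ...) {
  cat(sprintf(
    "<memory_plan> %d group(s), %g bytes/wavevector, budget %g bytes\n",
    x$n_groups, x$bytes_per_wavevector, x$budget_bytes))
  invisible(x)
}
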
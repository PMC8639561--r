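#' Azimuthal average onto wave-number rings
#'
#' For an isotropic sample the structure function depends on `|q|` only, so
#' the 2D `d(m, q)` maps are collapsed onto rings of constant wave number.
#' Ring `r` collects the half-plane wave vectors with
#' `round(|q| / dq) == r`, `dq = 2*pi / (max(H, W) * pixel_size)` (round half
#' to even). Each wave vector contributes with its Hermitian multiplicity, so
#' the ring mean equals the unweighted mean over the reconstructed full plane.
#' The `q = 0` (DC) entry is always excluded; empty rings are dropped.
#'
#' @param sf a `structure_function`.
#' @return An object of class `radial_structure`: list with `q_centers`
#'   (ring-center magnitudes, rad/m), `d_radial` (`R x M` matrix, rings by
#'   lags), `ring_counts` (full-plane pixel counts per ring), `lags`, `dt`,
#'   and the originating `algorithm` label.
#' @export
azimuthal_average <- function(sf) {
  stopifnot(inherits(sf, "structure_function"))
  grid <- sf$grid
  dq <- 2 * pi / (max(grid$H, grid$W) * grid$pixel_size)
  ring <- round(grid$q_magnitudes / dq)
  keep <- seq_along(ring)[-1L]                 # drop q = 0 (flat index 1)
  ring_v <- as.vector(ring)[keep]
  w <- as.vector(grid$multiplicity)[keep]
  M <- length(sf$lags)
  dmat <- matrix(sf$d, nrow = M)               # lags x nq, column-major grid
  wsum <- rowsum(w, ring_v)
  ids <- as.numeric(rownames(wsum))
  d_radial <- matrix(0, length(ids), M)
  for (i in seq_len(M)) {
    d_radial[, i] <- rowsum(w * dmat[i, keep], ring_v) / wsum
  }
  structure(
    list(q_centers = ids * dq, d_radial = d_radial,
         ring_counts = as.vector(wsum), lags = sf$lags, dt = sf$dt,
         algorithm = sf$algorithm, dq = dq),
    class = "radial_structure"
  )
}

#' @export
print.radial_structure <- function(x, ...) {
  cat(sprintf(
    "<radial_structure> %d rings (q in [%.3g, %.3g] rad/m) x %d lags\n",
    length(x$q_centers), min(x$q_centers), max(x$q_centers), length(x$lags)))
  invisible(x)
}

#' Tidy a radial structure function into a long tibble
#'
#' @param x a `radial_structure`.
#' @param ... unused.
#' @return A tibble with columns `q` (rad/m), `lag` (frames), `lag_time_s`,
#'   `d` — one row per ring and lag.
#' @method tidy radial_structure
#' @export
tidy.radial_structure <- function(x, ...) {
  R <- length(x$q_centers); M <- length(x$lags)
  tibble::tibble(
    q = rep(x$q_centers, times = M),
    lag = rep(x$lags, each = R),
    lag_time_s = rep(x$lags * x$dt, each = R),
    d = as.vector(x$d_radial)
  )
}

#' Plot ring-averaged structure functions against lag time
#'
#' One curve per wave-number ring, on log-log axes — the standard DDM
#' diagnostic in which single-exponential relaxation shows as a rise to a
#' plateau with a q-dependent knee.
#'
#' @param object a `radial_structure`.
#' @param rings optional integer indices of rings to draw (default: up to 8,
#'   evenly spaced).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot radial_structure
#' @export
autoplot.radial_structure <- function(object, rings = NULL, ...) {
  df <- tidy(object)
  df <- df[df$lag >= 1L, ]
  if (is.null(rings))
    rings <- unique(round(seq(1, length(object$q_centers),
                              length.out = min(8, length(object$q_centers)))))
  qsel <- object$q_centers[rings]
  df <- df[df$q %in% qsel, ]
  df$ring <- factor(signif(df$q, 3))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_time_s, y = .data$d,
                                   colour = .data$ring)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag time (s)", y = "d(q, t)",
                  colour = "q (rad/m)")
}
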
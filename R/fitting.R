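#' Fit a single-exponential intermediate scattering function per ring
#'
#' For simple diffusion the intermediate scattering function decays as
#' `exp(-t / tau(q))`, so the ring-averaged structure function follows
#'
#'   `d(q, t) = A(q) * (1 - exp(-t / tau(q))) + B(q)`
#'
#' with amplitude `A` (signal strength at that wave number), baseline `B`
#' (camera noise floor) and decay time `tau`. Each ring is fitted by
#' Levenberg-Marquardt least squares over the lags `m >= 1` (`d(0) = 0`
#' carries no information and is not part of the model), with bounds
#' `A >= 0`, `tau > 0`. Starting values: `B0 = min(d)`, `A0 = max - min`,
#' `tau0` the earliest time at which `d` exceeds `B0 + (1 - 1/e) * A0`
#' (mid-range time if never reached).
#'
#' Rings whose fit does not converge, hits the bounds, or carries no dynamic
#' range are flagged via `converged = FALSE` and kept in the table — never
#' silently dropped.
#'
#' When more than `max_lags` lags are available, the fit by default uses a
#' log-spaced subset of them. With a dense uniform lag set almost every point
#' sits on the saturated plateau, so an unweighted fit lets plateau-level
#' statistical noise (the most correlated part of the estimate) dominate the
#' decay time; log spacing balances the weight per decade of lag time, the
#' usual practice when fitting relaxation curves spanning decades.
#'
#' @param rad a `radial_structure` with at least 4 lags `m >= 1`.
#' @param lag_sampling `"log"` (default) to fit on at most `max_lags`
#'   log-spaced lags, or `"all"` to use every available lag.
#' @param max_lags lag budget for `lag_sampling = "log"`.
#' @return An object of class `isf_fit`: a list with `rings` (tibble with
#'   columns `q`, `A`, `B`, `tau`, `resid_norm`, `converged`), `dt`, and a
#'   `diffusion` slot filled by [fit_diffusion()].
#' @export
fit_isf <- function(rad, lag_sampling = c("log", "all"), max_lags = 64L) {
  stopifnot(inherits(rad, "radial_structure"))
  lag_sampling <- match.arg(lag_sampling)
  sel <- rad$lags >= 1L
  if (lag_sampling == "log" && sum(sel) > max_lags) {
    pos <- rad$lags[sel]
    want <- unique(round(exp(seq(log(min(pos)), log(max(pos)),
                                 length.out = max_lags))))
    sel <- sel & rad$lags %in% want
  }
  t <- rad$lags[sel] * rad$dt
  if (length(t) < 4L)
    stop("need at least 4 lags with m >= 1 to fit 3 parameters", call. = FALSE)
  R <- length(rad$q_centers)
  out <- vector("list", R)
  for (r in seq_len(R)) {
    y <- rad$d_radial[r, sel]
    out[[r]] <- fit_one_ring(t, y)
  }
  rings <- tibble::tibble(
    q = rad$q_centers,
    A = vapply(out, `[[`, 0, "A"),
    B = vapply(out, `[[`, 0, "B"),
    tau = vapply(out, `[[`, 0, "tau"),
    resid_norm = vapply(out, `[[`, 0, "resid_norm"),
    converged = vapply(out, `[[`, NA, "converged"),
    n_modes = as.numeric(rad$ring_counts)
  )
  structure(list(rings = rings, dt = rad$dt,
                 t_max = max(rad$lags) * rad$dt, diffusion = NULL),
            class = "isf_fit")
}

fit_one_ring <- function(t, y) {
  failed <- list(A = NA_real_, B = NA_real_, tau = NA_real_,
                 resid_norm = NA_real_, converged = FALSE)
  rng <- max(y) - min(y)
  if (!all(is.finite(y)) || rng <= 1e-12 * max(abs(y), 1e-300)) {
    # flat curve: amplitude ~ 0, decay time unidentifiable
    failed$A <- 0; failed$B <- mean(y)
    failed$resid_norm <- sqrt(sum((y - mean(y))^2))
    return(failed)
  }
  B0 <- min(y)
  A0 <- rng
  thr <- B0 + (1 - exp(-1)) * A0
  idx <- which(y >= thr)
  tau0 <- if (length(idx)) t[idx[1]] else t[ceiling(length(t) / 2)]
  tau0 <- max(tau0, min(t))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * (1 - exp(-t / tau)) + B,
      start = list(A = A0, B = B0, tau = tau0),
      lower = c(A = 0, B = -Inf, tau = min(t) * 1e-6),
      upper = c(A = Inf, B = Inf, tau = max(t) * 1e6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(failed)
  p <- coef(fit)
  # a decay far outside the sampled time window is not a measurement: the
  # curve is then indistinguishable from a line (tau >> t_max) or a constant
  # (tau << t_min)
  conv <- isTRUE(fit$convInfo$isConv) &&
    p[["tau"]] > min(t) / 10 && p[["tau"]] < max(t) * 10
  list(A = p[["A"]], B = p[["B"]], tau = p[["tau"]],
       resid_norm = sqrt(sum(stats::resid(fit)^2)), converged = conv)
}

#' @export
print.isf_fit <- function(x, ...) {
  cat(sprintf("<isf_fit> %d rings, %d converged\n",
              nrow(x$rings), sum(x$rings$converged)))
  if (!is.null(x$diffusion))
    cat(sprintf("  D = %.4g m^2/s over q in [%.3g, %.3g] rad/m (%d rings)\n",
                x$diffusion$D, x$diffusion$q_min, x$diffusion$q_max,
                x$diffusion$n_rings))
  invisible(x)
}

#' Broom-style per-ring coefficients of an ISF fit
#' @param x an `isf_fit`.
#' @param ... unused.
#' @return The per-ring tibble (`q`, `A`, `B`, `tau`, `resid_norm`,
#'   `converged`).
#' @method tidy isf_fit
#' @export
tidy.isf_fit <- function(x, ...) x$rings

#' One-row summary of an ISF fit
#' @param x an `isf_fit`.
#' @param ... unused.
#' @return A tibble with ring counts and, if [fit_diffusion()] has been run,
#'   the diffusion coefficient, its fitted q-range and the log-log tau(q)
#'   slope.
#' @method glance isf_fit
#' @export
glance.isf_fit <- function(x, ...) {
  base <- tibble::tibble(n_rings = nrow(x$rings),
                         n_converged = sum(x$rings$converged))
  if (is.null(x$diffusion)) return(base)
  cbind(base, tibble::tibble(
    D = x$diffusion$D, q_min = x$diffusion$q_min, q_max = x$diffusion$q_max,
    n_fit_rings = x$diffusion$n_rings,
    loglog_slope = x$diffusion$loglog_slope))
}

#' Extract the diffusion coefficient from the decay times
#'
#' Brownian diffusion gives `tau(q) = 1 / (D * q^2)`. Rather than fitting the
#' log-log slope, `D` is obtained from the origin-constrained linear
#' regression of `1/tau` on `q^2` (closed form, no iterative solver),
#' restricted to converged rings inside `[q_min, q_max]`. The band should
#' exclude low-q rings whose decay exceeds the acquisition time and high-q
#' rings beyond the signal band. The log-log slope of `tau(q)` over the same
#' band is reported as a diagnostic (expected near -2 in the diffusive
#' regime); since the variance of a log decay time falls with both the number
#' of independent Fourier modes in the ring and the number of decorrelation
#' times spanned by the acquisition, the slope regression uses
#' inverse-variance weights `n_modes * t_max / tau` when the fit carries mode
#' counts (unweighted otherwise).
#'
#' @param fit an `isf_fit`.
#' @param q_min,q_max wave-number bounds in rad/m.
#' @return The `isf_fit` with its `diffusion` slot filled: `D` (m^2/s),
#'   `q_min`, `q_max`, `n_rings`, `loglog_slope`.
#' @export
fit_diffusion <- function(fit, q_min, q_max) {
  stopifnot(inherits(fit, "isf_fit"), q_min < q_max)
  r <- fit$rings
  use <- r$converged & r$q >= q_min & r$q <= q_max & r$tau > 0
  if (sum(use) < 2L)
    stop("need at least 2 converged rings in [", q_min, ", ", q_max,
         "] rad/m, found ", sum(use), call. = FALSE)
  x <- r$q[use]^2
  y <- 1 / r$tau[use]
  D <- sum(x * y) / sum(x * x)               # least squares through the origin
  w <- if ("n_modes" %in% names(r) && !is.null(fit$t_max)) {
    r$n_modes[use] * fit$t_max / r$tau[use]
  } else {
    rep(1, sum(use))
  }
  slope <- unname(coef(lm(log(r$tau[use]) ~ log(r$q[use]), weights = w))[2])
  fit$diffusion <- list(D = D, q_min = q_min, q_max = q_max,
                        n_rings = sum(use), loglog_slope = slope)
  fit
}

#' Plot decay times against wave number with the diffusive fit
#'
#' @param object an `isf_fit` (ideally after [fit_diffusion()]).
#' @param ... unused.
#' @return A ggplot object: log-log tau(q), converged rings filled, with the
#'   `1/(D q^2)` line overlaid when available.
#' @method autoplot isf_fit
#' @export
autoplot.isf_fit <- function(object, ...) {
  df <- object$rings[is.finite(object$rings$tau) & object$rings$tau > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$tau)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$converged)) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "q (rad/m)", y = expression(tau(q) ~ "(s)"))
  if (!is.null(object$diffusion)) {
    D <- object$diffusion$D
    qs <- exp(seq(log(min(df$q)), log(max(df$q)), length.out = 50))
    line <- tibble::tibble(q = qs, tau = 1 / (D * qs^2))
    p <- p + ggplot2::geom_line(data = line, colour = "red")
  }
  p
}
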
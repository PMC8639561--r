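isf_curve <- function(t, A, B, tau) A * (1 - exp(-t / tau)) + B

test_that("noiseless single-exponential parameters are recovered exactly", {
  t <- (1:50) * 0.1
  rad <- make_radial(q = c(1e5, 2e5), lags = 0:50, dt = 0.1,
                     dmat = rbind(isf_curve(t, 10, 2, 0.5),
                                  isf_curve(t, 20, 1, 0.1)))
  rad$d_radial <- cbind(0, rad$d_radial)   # prepend the d(0) = 0 column
  fit <- fit_isf(rad)
  expect_true(all(fit$rings$converged))
  expect_equal(fit$rings$A, c(10, 20), tolerance = 1e-6)
  expect_equal(fit$rings$B, c(2, 1), tolerance = 1e-6)
  expect_equal(fit$rings$tau, c(0.5, 0.1), tolerance = 1e-6)
})

test_that("noisy curves agree with an independent grid-search oracle", {
  t <- (1:50) * 0.1
  set.seed(61)
  y <- isf_curve(t, A = 10, B = 2, tau = 0.5) + rnorm(50, 0, 0.5)
  # independent oracle: exhaustive grid search over (A, B, tau)
  grid <- expand.grid(A = seq(8, 12, 0.05), B = seq(1, 3, 0.05),
                      tau = seq(0.2, 1, 0.005))
  sse <- vapply(seq_len(nrow(grid)), function(i)
    sum((y - isf_curve(t, grid$A[i], grid$B[i], grid$tau[i]))^2), 0)
  best <- grid[which.min(sse), ]
  rad <- make_radial(q = 1e5, dmat = matrix(c(0, y), 1), lags = 0:50,
                     dt = 0.1)
  fit <- fit_isf(rad)
  expect_true(fit$rings$converged)
  expect_equal(fit$rings$A, best$A, tolerance = 0.05)
  expect_equal(fit$rings$B, best$B, tolerance = 0.05)
  expect_equal(fit$rings$tau, best$tau, tolerance = 0.02)
})

test_that("a constant curve yields zero amplitude and an unidentifiable tau", {
  rad <- make_radial(q = 1e5, dmat = matrix(c(0, rep(4, 20)), 1),
                     lags = 0:20, dt = 0.1)
  fit <- fit_isf(rad)
  expect_false(fit$rings$converged)
  expect_equal(fit$rings$A, 0)
  expect_equal(fit$rings$B, 4)
})

test_that("fewer than four informative lags is an input error", {
  rad <- make_radial(q = 1e5, dmat = matrix(c(0, 1, 2, 3), 1), lags = 0:3,
                     dt = 0.1)
  expect_error(fit_isf(rad), "at least 4 lags")
})

test_that("exact diffusive scaling recovers D to machine precision", {
  D <- 1e-10
  q <- seq(2e5, 2e6, length.out = 10)
  fit <- structure(list(rings = tibble::tibble(
    q = q, A = 1, B = 0, tau = 1 / (D * q^2), resid_norm = 0,
    converged = TRUE), dt = 0.1, diffusion = NULL), class = "isf_fit")
  out <- fit_diffusion(fit, min(q), max(q))
  expect_equal(out$diffusion$D, D, tolerance = 1e-12)
  expect_equal(out$diffusion$loglog_slope, -2, tolerance = 1e-9)
})

test_that("noisy decay times match the closed-form regression oracle", {
  D <- 1e-10
  q <- seq(2e5, 2e6, length.out = 20)
  set.seed(62)
  tau <- (1 / (D * q^2)) * exp(rnorm(20, 0, 0.05))
  fit <- structure(list(rings = tibble::tibble(
    q = q, A = 1, B = 0, tau = tau, resid_norm = 0, converged = TRUE),
    dt = 0.1, diffusion = NULL), class = "isf_fit")
  out <- fit_diffusion(fit, min(q), max(q))
  oracle <- sum(q^2 * (1 / tau)) / sum(q^4)   # through-origin least squares
  expect_equal(out$diffusion$D, oracle, tolerance = 1e-12)
  expect_equal(out$diffusion$D, D, tolerance = 0.05)
})

test_that("non-converged rings are excluded and sparse ranges rejected", {
  q <- c(1e5, 2e5, 3e5)
  fit <- structure(list(rings = tibble::tibble(
    q = q, A = 1, B = 0, tau = c(1, 2, 3),
    resid_norm = 0, converged = c(TRUE, FALSE, TRUE)),
    dt = 0.1, diffusion = NULL), class = "isf_fit")
  expect_error(fit_diffusion(fit, 1.5e5, 2.5e5), "at least 2")
  out <- fit_diffusion(fit, 0.5e5, 3.5e5)
  expect_identical(out$diffusion$n_rings, 2L)
})

test_that("tidy and glance expose the fit in broom shape", {
  q <- seq(2e5, 1e6, length.out = 5)
  D <- 2e-11
  fit <- structure(list(rings = tibble::tibble(
    q = q, A = 1, B = 0, tau = 1 / (D * q^2), resid_norm = 0,
    converged = TRUE), dt = 0.1, diffusion = NULL), class = "isf_fit")
  expect_true(all(c("q", "A", "B", "tau", "resid_norm", "converged")
                  %in% names(tidy(fit))))
  expect_identical(glance(fit)$n_converged, 5L)
  g <- glance(fit_diffusion(fit, min(q), max(q)))
  expect_equal(g$D, D, tolerance = 1e-10)
})
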
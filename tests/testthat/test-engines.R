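test_that("the two-frame 2x2 case matches the hand-computed DFT table", {
  # I0 has a unit pixel at (1,1), I1 at (2,2); the difference transform has
  # zero DC and weight 4 on the two mixed-frequency entries
  frames <- array(0, c(2, 2, 2))
  frames[1, 1, 1] <- 1
  frames[2, 2, 2] <- 1
  s <- image_series(frames, dt = 1, pixel_size = 1)
  sf <- structure_naive(s, lags = 1)
  expect_equal(sf$d[1, , ], matrix(c(0, 4, 4, 0), 2, 2), tolerance = 1e-14)
  expect_identical(sf$pair_counts, 1L)
})

test_that("identical frames give an identically zero structure function", {
  s <- image_series(array(7, c(5, 4, 4)), dt = 1, pixel_size = 1)
  for (engine in c("naive", "direct", "wk")) {
    sf <- structure_function(s, engine)
    expect_equal(max(abs(sf$d)), 0)
  }
})

test_that("lag zero is exactly zero and out-of-range lags are rejected", {
  s <- rand_series(6, 4, 4, seed = 2)
  sp <- spatial_fft(s)
  expect_equal(max(abs(structure_naive(s, lags = 0)$d)), 0)
  expect_equal(max(abs(structure_direct(sp, lags = 0)$d)), 0)
  expect_equal(max(abs(structure_wk(sp, lags = 0)$d)), 0)
  expect_error(structure_naive(s, lags = 6), "lags must lie")
  expect_error(structure_wk(sp, lags = -1), "lags must lie")
})

test_that("cached-spectra engine reproduces the naive oracle exactly", {
  s <- rand_series(16, 8, 8, seed = 31)
  ref <- structure_naive(s)
  sf <- structure_direct(spatial_fft(s))
  expect_lt(rel_max_dev(ref$d, sf$d), 1e-12)
  expect_identical(sf$pair_counts, ref$pair_counts)
})

test_that("Wiener-Khinchin engine reproduces the naive oracle", {
  s <- rand_series(64, 16, 16, seed = 32)
  ref <- structure_naive(s)
  sf <- structure_wk(spatial_fft(s))
  expect_lt(rel_max_dev(ref$d, sf$d), 1e-9)
})

test_that("all three engines agree across sizes (randomized, fixed seeds)", {
  cases <- list(c(N = 32, H = 16, W = 16, seed = 41),
                c(N = 128, H = 8, W = 8, seed = 42),
                c(N = 5, H = 6, W = 10, seed = 43))
  for (cs in cases) {
    s <- rand_series(cs["N"], cs["H"], cs["W"], seed = cs["seed"])
    ref <- structure_naive(s)
    expect_lt(rel_max_dev(ref$d, structure_direct(spatial_fft(s))$d), 1e-9)
    expect_lt(rel_max_dev(ref$d, structure_wk(spatial_fft(s))$d), 1e-9)
    expect_gt(min(ref$d), -1e-9 * max(ref$d))  # nonnegativity
  }
})

test_that("two frames collapse the expansion to |I0hat - I1hat|^2", {
  s <- rand_series(2, 6, 6, seed = 44)
  sp <- spatial_fft(s)
  expected <- Mod(sp$spectra[1, , ] - sp$spectra[2, , ])^2
  sf <- structure_wk(sp, lags = 1)
  expect_lt(rel_max_dev(expected, sf$d[1, , ]), 1e-12)
})

test_that("chunked execution is invariant in the group count", {
  s <- rand_series(24, 8, 8, seed = 45)
  sp <- spatial_fft(s)
  ref <- structure_wk(sp)
  for (G in c(2L, 4L, 7L)) {
    plan <- plan_memory(24, 8, 8, budget_bytes = 1e9, n_groups = G)
    sf <- structure_wk(sp, plan = plan)
    expect_lt(rel_max_dev(ref$d, sf$d), 1e-12)
    expect_identical(sf$work$groups, G)
  }
  # and through the orchestrator, which recomputes spatial FFTs per group
  sfo <- structure_function(s, "wk", n_groups = 3)
  expect_lt(rel_max_dev(ref$d, sfo$d), 1e-12)
  expect_identical(sfo$work$spatial_ffts, 3L * 24L)
})

test_that("the complex cross term cancels to a real result over the full plane", {
  # per wave vector the cross term is complex; Hermitian symmetry pairs +q
  # with -q so the full-plane assembly through the temporal route is real up
  # to rounding
  s <- rand_series(12, 6, 6, seed = 46)
  sp <- spatial_fft(s)
  N <- 12; H <- 6; W <- 6
  full <- array(0i, c(N, H, W))
  for (n in 1:N) full[n, , ] <- ddmsf:::hermitian_full_plane(sp$spectra[n, , ], H, W)
  Sm <- matrix(full, nrow = N)
  m <- 3
  C <- vapply(seq_len(ncol(Sm)),
              function(j) lagged_autocorrelation(Sm[, j])[m + 1], 0i)
  p <- Mod(Sm)^2
  d_complex <- (colSums(p[1:(N - m), , drop = FALSE]) +
                colSums(p[(1 + m):N, , drop = FALSE]) - 2 * C) / (N - m)
  total <- sum(d_complex)
  expect_lt(abs(Im(total)), 1e-10 * abs(Re(total)))
  # and the engine's assembled d agrees with the real part, elementwise on
  # the half plane
  sf <- structure_wk(sp, lags = m)
  firstcols <- matrix(Re(d_complex), H, W)[, 1:(W / 2 + 1)]
  expect_lt(rel_max_dev(firstcols, sf$d[1, , ]), 1e-10)
})

test_that("work counters embody the complexity claims", {
  for (N in c(32L, 64L, 128L)) {
    s <- rand_series(N, 8, 8, seed = N)
    nq <- 8L * 5L
    lags_all <- 0:(N - 1)
    lags_few <- c(0, 1, 2, 5)
    wk_all <- structure_function(s, "wk", lags = lags_all)
    wk_few <- structure_function(s, "wk", lags = lags_few)
    # 2 temporal transforms per wave vector per group, independent of lags
    expect_identical(wk_all$work$temporal_ffts, 2L * nq)
    expect_identical(wk_few$work$temporal_ffts, 2L * nq)
    expect_identical(wk_all$work$spatial_ffts, N)
    wk_g <- structure_function(s, "wk", n_groups = 4)
    expect_identical(wk_g$work$temporal_ffts, 2L * nq)
    expect_identical(wk_g$work$spatial_ffts, 4L * N)
    # direct engine's elementwise pass count grows as sum(N - m)
    dr <- structure_function(s, "direct", lags = lags_all)
    expect_identical(dr$work$elementwise_passes, sum(N - lags_all[-1]))
    dr2 <- structure_function(s, "direct", lags = lags_few)
    expect_identical(dr2$work$elementwise_passes, sum(N - c(1L, 2L, 5L)))
    # naive engine spends one spatial FFT per retained frame pair
    nv <- structure_naive(s, lags = lags_few)
    expect_identical(nv$work$spatial_ffts, sum(N - c(1L, 2L, 5L)))
  }
})
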
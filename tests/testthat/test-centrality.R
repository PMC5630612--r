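test_that("window enumeration drops the trailing remainder", {
  w <- make_windows(1190, 83, 5)
  expect_equal(w$n_windows, (1190 - 83) %/% 5 + 1)   # enumeration oracle: 222
  expect_equal(w$n_windows, 222L)
  expect_equal(w$starts[1], 1L)
  expect_equal(diff(w$starts), rep(5L, 221))
  expect_true(max(w$starts) + 83 - 1 <= 1190)
  expect_equal(make_windows(100, 60, 5)$n_windows, 9L)
  expect_equal(make_windows(83, 83, 5)$n_windows, 1L)
  expect_error(make_windows(50, 60), "window length")
})

test_that("window normalization yields an implicit Pearson correlation matrix", {
  set.seed(11)
  Xw <- matrix(rnorm(30 * 83), 30, 83)
  Z <- normalize_window(Xw)
  expect_equal(rowMeans(Z), rep(0, 30), tolerance = 1e-12)
  C <- tcrossprod(Z)
  expect_equal(diag(C), rep(1, 30), tolerance = 1e-10)
  # dense correlation oracle: entries are exactly the Pearson correlations
  expect_equal(C, cor(t(Xw)), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(C[1, 2], cor(Xw[1, ], Xw[2, ]), tolerance = 1e-10)
  # identical rows have implicit correlation one
  X2 <- rbind(Xw[1, ], Xw[1, ])
  expect_equal(tcrossprod(normalize_window(X2))[1, 2], 1, tolerance = 1e-10)
  Xw[3, ] <- 5
  expect_error(normalize_window(Xw), "voxel row")
})

test_that("stationary basis matches dense eigendecomposition and reconstructs C", {
  set.seed(12)
  X <- normalize_window(matrix(rnorm(100 * 300), 100, 300))
  b <- stationary_basis(X, 10)
  C <- tcrossprod(X)
  e <- eigen(C, symmetric = TRUE)
  expect_equal(b$values, e$values[1:10], tolerance = 1e-8)
  expect_lt(max(abs(abs(colSums(b$vectors * e$vectors[, 1:10])) - 1)), 1e-8)
  # orthonormality
  expect_equal(crossprod(b$vectors), diag(10), tolerance = 1e-8, ignore_attr = TRUE)
  # full-rank limit reconstructs C
  bf <- stationary_basis(X, 100)
  rec <- bf$vectors %*% (bf$values * t(bf$vectors))
  expect_lt(max(abs(rec - C)), 1e-8)
  # centered rows make X rank-deficient: requesting beyond rank warns
  Xs <- normalize_window(matrix(rnorm(20 * 10), 20, 10))
  expect_warning(bs <- stationary_basis(Xs, 10), "numerical rank")
  expect_lt(bs$M, 10)
})

test_that("the centered matvec equals the dense centered matrix product", {
  set.seed(13)
  nv <- 80; nt <- 40
  X <- normalize_window(matrix(rnorm(nv * 200), nv, 200))
  b <- stationary_basis(X, 7)
  Xw <- normalize_window(matrix(rnorm(nv * nt), nv, nt))
  Cd <- dense_centered(Xw, b)
  for (s in 1:5) {
    w <- rnorm(nv)
    expect_equal(centered_matvec(Xw, b, w), as.vector(Cd %*% w), tolerance = 1e-8)
  }
  # M = 0 reduces to the plain windowed product
  b0 <- stationary_basis(X, 0)
  w <- rnorm(nv)
  expect_equal(centered_matvec(Xw, b0, w), as.vector(tcrossprod(Xw) %*% w),
               tolerance = 1e-10)
  # window equal to the full run with full-rank basis gives the zero operator
  bfull <- suppressWarnings(stationary_basis(X, min(dim(X))))
  expect_lt(max(abs(centered_matvec(X, bfull, w))), 1e-6)
  expect_error(centered_matvec(Xw, b, rnorm(nv + 1)), "length")
})

test_that("dominant patterns match dense eigendecomposition up to sign", {
  # two perfectly correlated voxels, no centering: closed form
  Xw <- normalize_window(rbind(sin(1:50) + 1, 2 * sin(1:50) + 5))
  dp <- dominant_pattern(Xw)
  expect_equal(abs(dp$u), rep(1 / sqrt(2), 2), tolerance = 1e-8)
  expect_equal(dp$lambda, 2, tolerance = 1e-8)
  # planted rank-1 window recovers the planted map up to sign
  set.seed(14)
  a <- rnorm(40); a <- a / sqrt(sum(a^2))
  z <- rnorm(30); z <- z - mean(z); z <- z / sqrt(sum(z^2))
  dp1 <- dominant_pattern(a %o% z)
  expect_lt(min(sum(abs(dp1$u - a)), sum(abs(dp1$u + a))), 1e-6)
  # random centered instances against the dense oracle, both eig modes
  X <- normalize_window(matrix(rnorm(50 * 200), 50, 200))
  b <- stationary_basis(X, 5)
  for (mode in c("magnitude", "algebraic")) {
    Xw <- normalize_window(matrix(rnorm(50 * 83), 50, 83))
    dpo <- dominant_pattern(Xw, b, eig_mode = mode)
    ref <- dense_leading(dense_centered(Xw, b), mode)
    expect_equal(abs(dpo$lambda), abs(ref$lambda), tolerance = 1e-6)
    expect_lt(min(sqrt(sum((dpo$u - ref$u)^2)), sqrt(sum((dpo$u + ref$u)^2))), 1e-6)
  }
})

test_that("the ARPACK route agrees with the projection solver", {
  set.seed(15)
  X <- normalize_window(matrix(rnorm(60 * 150), 60, 150))
  b <- stationary_basis(X, 4)
  Xw <- normalize_window(matrix(rnorm(60 * 40), 60, 40))
  p1 <- dominant_pattern(Xw, b, method = "projection")
  p2 <- dominant_pattern(Xw, b, method = "arpack")
  expect_equal(abs(p1$lambda), abs(p2$lambda), tolerance = 1e-6)
  expect_lt(min(sqrt(sum((p1$u - p2$u)^2)), sqrt(sum((p1$u + p2$u)^2))), 1e-5)
})

test_that("per-subject extraction aligns signs and tracks planted structure", {
  # noiseless single-state data: every window sees the same rank-1 structure
  sim <- simulate_dfc_dataset(n_subjects = 1, grid_dim = c(10, 10, 8), n_states = 1,
                              T = 240, dwell = 10, snr = Inf, seed = 21)
  gt <- sim$ground_truth
  ts <- mask_timeseries(sim$subjects[[1]], sim$mask, tr = 0.72, affine = gt$affine)
  dp <- run_subject(ts, spec = make_windows(240, 83, 20), M = 0)
  cs <- crossprod(dp$u)
  expect_true(all(cs > 0.99))                 # all windows mutually aligned
  expect_gt(mean(abs(crossprod(dp$u, gt$patterns))), 0.99)
  # consecutive-window sign convention: nonnegative consecutive cosines
  sim2 <- cached_sim()
  ts2 <- mask_timeseries(sim2$subjects[[1]], sim2$mask, tr = 0.72,
                         affine = sim2$ground_truth$affine)
  ts2 <- preprocess_run(ts2, n_discard = 0)
  dp2 <- run_subject(ts2, spec = make_windows(ncol(ts2$data), 83, 20), M = 10)
  consec <- colSums(dp2$u[, -1] * dp2$u[, -ncol(dp2$u)])
  expect_true(all(consec >= 0))
  expect_equal(sqrt(colSums(dp2$u^2)), rep(1, ncol(dp2$u)), tolerance = 1e-10)
})
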
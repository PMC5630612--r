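test_that("discarding initial volumes drops exactly the leading columns", {
  ts <- random_ts(5, 1200)
  out <- discard_initial(ts, 10)
  expect_equal(ncol(out$data), 1190L)
  expect_equal(out$data, ts$data[, 11:1200])
  expect_identical(discard_initial(ts, 0), ts)
  short <- random_ts(3, 50)
  expect_equal(ncol(discard_initial(short, 49)$data), 1L)
  expect_error(discard_initial(short, 50), "smaller than T")
})

test_that("polynomial detrending matches an explicit least-squares projection", {
  T <- 200
  tt <- seq_len(T)
  ts <- random_ts(6, T, seed = 4)
  # an exactly-polynomial row must vanish
  ts$data[1, ] <- 3 - 0.2 * tt + 0.01 * tt^2
  out <- detrend_poly(ts, 2)
  expect_lt(max(abs(out$data[1, ])), 1e-8)
  # orthogonality to the polynomial regressors
  P <- cbind(1, tt, tt^2)
  expect_lt(max(abs(out$data %*% P)) / max(abs(out$data)), 1e-6)
  # residual equals the brute-force per-row normal-equations solve
  for (r in 2:4) {
    beta <- solve(crossprod(P), crossprod(P, ts$data[r, ]))
    expect_equal(out$data[r, ], as.vector(ts$data[r, ] - P %*% beta),
                 tolerance = 1e-10)
  }
  # idempotence
  again <- detrend_poly(out, 2)
  expect_lt(max(abs(again$data - out$data)), 1e-10)
  expect_error(detrend_poly(random_ts(2, 3), 2), "too short")
})

test_that("confound regression equals dense per-voxel OLS", {
  T <- 150
  ts <- random_ts(8, T, seed = 5)
  set.seed(6)
  Q <- matrix(rnorm(T * 8), T, 8)
  out <- regress_confounds(ts, Q)
  X <- cbind(1, Q)
  for (r in c(1, 4, 8)) {
    beta <- solve(crossprod(X), crossprod(X, ts$data[r, ]))
    expect_equal(out$data[r, ], as.vector(ts$data[r, ] - X %*% beta),
                 tolerance = 1e-8)
  }
  expect_lt(max(abs(out$data %*% Q)), 1e-6)
  # a confound equal to a voxel's own row annihilates that row
  out2 <- regress_confounds(ts, cbind(ts$data[3, ]))
  expect_lt(max(abs(out2$data[3, ])), 1e-8)
  # Q = 0 mean-centers only
  out3 <- regress_confounds(ts, NULL)
  expect_equal(out3$data, ts$data - rowMeans(ts$data))
  # rank-deficient confounds are refused with the collinear column named
  expect_error(regress_confounds(ts, cbind(a = Q[, 1], b = 2 * Q[, 1])),
               "rank deficient")
})

test_that("band-pass preserves mid-band and rejects out-of-band sinusoids", {
  T <- 1190; tr <- 0.72
  tt <- (seq_len(T) - 1) * tr
  amp_at <- function(x, f) {
    # FFT amplitude oracle at the probe frequency
    sp <- abs(fft(x))[seq_len(T %/% 2)]
    fr <- (seq_len(T %/% 2) - 1) / (T * tr)
    sp[which.min(abs(fr - f))]
  }
  mk <- function(f) {
    ts <- random_ts(1, T)
    ts$data[1, ] <- sin(2 * pi * f * tt)
    ts
  }
  f_mid <- 0.05; f_lo <- 0.005; f_hi <- 0.30
  r_mid <- amp_at(bandpass(mk(f_mid))$data[1, ], f_mid) / amp_at(mk(f_mid)$data[1, ], f_mid)
  r_lo <- amp_at(bandpass(mk(f_lo))$data[1, ], f_lo) / amp_at(mk(f_lo)$data[1, ], f_lo)
  r_hi <- amp_at(bandpass(mk(f_hi))$data[1, ], f_hi) / amp_at(mk(f_hi)$data[1, ], f_hi)
  expect_gt(r_mid, 0.95)
  expect_lt(r_lo, 0.20)
  expect_lt(r_hi, 0.20)
  z <- random_ts(2, 300); z$data[] <- 0
  expect_equal(bandpass(z)$data, z$data)
  expect_error(bandpass(random_ts(1, 100), high = 0.8), "Nyquist")
})

test_that("global signal regression matches an explicit OLS on the mean timecourse", {
  ts <- random_ts(10, 120, seed = 8)
  out <- global_signal_regress(ts)
  g <- colMeans(ts$data)
  X <- cbind(1, g)
  for (r in c(2, 7)) {
    beta <- solve(crossprod(X), crossprod(X, ts$data[r, ]))
    expect_equal(out$data[r, ], as.vector(ts$data[r, ] - X %*% beta),
                 tolerance = 1e-8)
  }
  expect_lt(max(abs(out$data %*% (g - mean(g)))), 1e-6)
  # identical rows collapse to zero
  same <- random_ts(4, 60)
  same$data <- matrix(rep(same$data[1, ], 4), 4, byrow = TRUE)
  expect_lt(max(abs(global_signal_regress(same)$data)), 1e-10)
  # antisymmetric pair has zero global mean: rows only lose their means
  anti <- random_ts(2, 60)
  anti$data[2, ] <- -anti$data[1, ]
  res <- global_signal_regress(anti)
  expect_equal(res$data, anti$data - rowMeans(anti$data), tolerance = 1e-10)
})

test_that("gaussian smoothing has the stated FWHM and conserves mass", {
  dim3 <- c(21, 21, 15)
  img <- array(0, c(dim3, 1))
  img[11, 11, 8, 1] <- 1
  aff <- diag(c(2, 2, 2, 1))                 # 2 mm voxels
  sm <- smooth_gaussian(img, fwhm = 5, affine = aff)
  expect_equal(sum(sm), 1, tolerance = 1e-3) # mass conserved
  prof <- sm[, 11, 8, 1]
  half <- max(prof) / 2
  # linear-interpolated half-maximum crossings, in mm
  above <- which(prof >= half)
  x <- seq_along(prof)
  lhs <- min(above); rhs <- max(above)
  xl <- lhs - 1 + (half - prof[lhs - 1]) / (prof[lhs] - prof[lhs - 1])
  xr <- rhs + (prof[rhs] - half) / (prof[rhs] - prof[rhs + 1])
  expect_equal((xr - xl) * 2, 5, tolerance = 0.25)
  # identity and constant-volume contracts
  expect_identical(smooth_gaussian(img, 0, aff), img)
  const <- array(3, c(9, 9, 9, 1))
  smc <- smooth_gaussian(const, 5, aff)
  expect_equal(smc[5, 5, 5, 1], 3, tolerance = 1e-10)
  expect_error(smooth_gaussian(img, -1, aff), "non-negative")
})

test_that("the full preprocessing chain is approximately idempotent", {
  ts <- random_ts(12, 400, seed = 10)
  once <- preprocess_run(ts, n_discard = 5)
  twice <- preprocess_run(once, n_discard = 0)
  rel <- sqrt(sum((twice$data - once$data)^2)) / sqrt(sum(once$data^2))
  # linear stages are exactly idempotent; the band-pass is only approximately
  # so (the squared transition-band response attenuates edge frequencies again)
  expect_lt(rel, 0.2)
  expect_equal(attr(once, "prep")$order,
               c("discard", "detrend", "confounds", "bandpass", "gsr"))
})
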
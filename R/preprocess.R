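#' Discard initial volumes
#'
#' Drops the first `n_discard` timepoints so the signal is at steady-state
#' magnetization (e.g. 1200 volumes with 10 discarded leaves T = 1190).
#'
#' @param ts a [voxel_ts].
#' @param n_discard number of leading timepoints to drop.
#' @return A [voxel_ts] with `T - n_discard` timepoints.
#' @export
discard_initial <- function(ts, n_discard = 10L) {
  stopifnot(inherits(ts, "voxel_ts"))
  n_discard <- as.integer(n_discard)
  if (n_discard < 0L) stopf("n_discard must be >= 0")
  if (n_discard >= ncol(ts$data))
    stopf("n_discard (%d) must be smaller than T (%d)", n_discard, ncol(ts$data))
  if (n_discard == 0L) return(ts)
  ts$data <- ts$data[, -(seq_len(n_discard)), drop = FALSE]
  ts
}

#' Polynomial detrending
#'
#' Removes, per voxel, the least-squares projection onto polynomial time trends
#' up to `order` (default quadratic: constant, linear and quadratic terms).
#' Each output row is orthogonal to those regressors.
#'
#' @param ts a [voxel_ts].
#' @param order polynomial order (2 = linear + quadratic trends).
#' @return Detrended [voxel_ts].
#' @export
detrend_poly <- function(ts, order = 2L) {
  stopifnot(inherits(ts, "voxel_ts"))
  T <- ncol(ts$data)
  if (T < order + 2L) stopf("T (%d) too short for polynomial order %d", T, order)
  tt <- seq_len(T)
  P <- cbind(1, stats::poly(tt, degree = order))  # orthogonal basis, well conditioned
  ts$data <- residualize(ts$data, P)
  ts
}

#' Nuisance regression
#'
#' Regresses a set of confound timecourses (plus an implicit intercept) out of
#' every voxel's signal by ordinary least squares; the output rows are the OLS
#' residuals, orthogonal to every confound column.
#'
#' @param ts a [voxel_ts].
#' @param confounds numeric `T x Q` matrix (e.g. motion parameters, mean white
#'   matter and CSF signals). `Q = 0` (NULL or zero columns) mean-centers only.
#' @return Residualized [voxel_ts].
#' @export
regress_confounds <- function(ts, confounds = NULL) {
  stopifnot(inherits(ts, "voxel_ts"))
  T <- ncol(ts$data)
  if (is.null(confounds)) confounds <- matrix(numeric(0), nrow = T, ncol = 0)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != T)
    stopf("confounds have %d rows but T = %d", nrow(confounds), T)
  if (ncol(confounds) >= T) stopf("more confounds than timepoints")
  X <- cbind(`(intercept)` = 1, confounds)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    if (is.null(bad)) bad <- qx$pivot[(qx$rank + 1L):ncol(X)] - 1L
    stopf("confound matrix is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  ts$data <- residualize(ts$data, X)
  ts
}

## rows of `data` minus their least-squares projection onto columns of X
residualize <- function(data, X) {
  qx <- qr(X)
  ## residual of t(data) ~ X, computed once for all voxels
  t(qr.resid(qx, t(data)))
}

#' Band-pass filtering
#'
#' Zero-phase forward-backward Butterworth band-pass (order 5 in each
#' direction) restricted to the resting-state band, default
#' `[0.0167, 0.15]` Hz. Reflective padding suppresses edge transients before
#' the forward-backward pass.
#'
#' @param ts a [voxel_ts].
#' @param low,high band edges in Hz; `high` must stay below Nyquist = 1/(2 TR).
#' @param order Butterworth order per direction.
#' @return Filtered [voxel_ts].
#' @export
bandpass <- function(ts, low = 0.0167, high = 0.15, order = 5L) {
  stopifnot(inherits(ts, "voxel_ts"))
  fs <- 1 / ts$tr
  nyq <- fs / 2
  if (low <= 0 || high <= low) stopf("need 0 < low < high")
  if (high >= nyq) stopf("high (%g Hz) must be below Nyquist (%g Hz)", high, nyq)
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  T <- ncol(ts$data)
  pad <- min(T - 1L, 3L * (2L * order + 1L) * 10L)
  idx_pre <- seq(pad + 1L, 2L)
  idx_post <- seq(T - 1L, T - pad)
  filt_one <- function(x) {
    ## odd (point-reflected) extension, as is standard for zero-phase filtering
    ext <- c(2 * x[1] - x[idx_pre], x, 2 * x[T] - x[idx_post])
    y <- signal::filtfilt(bf, ext)
    y[(pad + 1L):(pad + T)]
  }
  ts$data <- t(apply(ts$data, 1L, filt_one))
  ts
}

#' Global signal regression
#'
#' Removes the across-voxel mean timecourse (the global signal) from every
#' voxel by per-voxel regression (with intercept), so each output row is
#' orthogonal to the global signal.
#'
#' @param ts a [voxel_ts] with at least 2 voxels.
#' @return [voxel_ts] with the global component regressed out.
#' @export
global_signal_regress <- function(ts) {
  stopifnot(inherits(ts, "voxel_ts"))
  if (nrow(ts$data) < 2L) stopf("need at least 2 voxels for a global signal")
  g <- colMeans(ts$data)
  if (sd(g) == 0) {
    ## zero/constant global mean: only the intercept is removable
    ts$data <- ts$data - rowMeans(ts$data)
    return(ts)
  }
  ts$data <- residualize(ts$data, cbind(1, g))
  ts
}

#' Spatial Gaussian smoothing
#'
#' Per-frame separable 3D Gaussian convolution with the kernel width given as
#' full width at half maximum in mm; voxel sizes are read from the affine.
#' Operates on the full volume (before masking), as spatial smoothing
#' conventionally does.
#'
#' @param img4d 4D array (x, y, z, t).
#' @param fwhm kernel FWHM in mm (scalar, isotropic in mm).
#' @param affine 4x4 voxel-to-mm affine (voxel sizes = column norms).
#' @return Smoothed 4D array.
#' @export
smooth_gaussian <- function(img4d, fwhm = 5, affine = diag(4)) {
  if (length(dim(img4d)) != 4L) stopf("`img4d` must be 4D")
  if (fwhm < 0) stopf("fwhm must be non-negative")
  if (fwhm == 0) return(img4d)
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  sigma_vox <- (fwhm / (2 * sqrt(2 * log(2)))) / vox
  out <- img4d
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 1e-8) next
    half <- max(1L, ceiling(4 * s))
    k <- exp(-(seq(-half, half))^2 / (2 * s^2))
    k <- k / sum(k)
    out <- convolve_axis(out, k, ax)
  }
  out
}

## separable 1D convolution along one spatial axis of a 4D array,
## with edge replication so a constant volume stays constant
convolve_axis <- function(a, k, axis) {
  d <- dim(a)
  half <- (length(k) - 1L) / 2L
  perm <- c(axis, setdiff(1:4, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, d[axis], prod(d[perm[-1]]))
  n <- nrow(m)
  mpad <- m[c(rep(1L, half), 1:n, rep(n, half)), , drop = FALSE]
  res <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) res <- res + k[j] * mpad[j:(j + n - 1L), , drop = FALSE]
  ap <- array(res, d[perm])
  aperm(ap, order(perm))
}

#' Full preprocessing chain
#'
#' Runs the fixed-order voxelwise preparation: discard initial volumes,
#' polynomial detrending, nuisance regression, band-pass filtering and global
#' signal regression. (Optional spatial smoothing and masking happen upstream,
#' in [mask_timeseries] / [smooth_gaussian].) The order used is recorded in the
#' result's `prep` attribute for provenance.
#'
#' @param ts a [voxel_ts] (already masked).
#' @param n_discard initial volumes to drop (default 10).
#' @param detrend_order polynomial detrend order (default 2).
#' @param confounds optional `T x Q` confound matrix, rows matching the input
#'   BEFORE discarding (the first `n_discard` rows are dropped alongside).
#' @param low,high band-pass edges in Hz.
#' @param global_signal apply global signal regression (default TRUE).
#' @return Preprocessed [voxel_ts] ready for windowed analysis.
#' @export
preprocess_run <- function(ts, n_discard = 10L, detrend_order = 2L,
                           confounds = NULL, low = 0.0167, high = 0.15,
                           global_signal = TRUE) {
  stopifnot(inherits(ts, "voxel_ts"))
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != ncol(ts$data))
      stopf("confounds rows (%d) must match T before discarding (%d)",
            nrow(confounds), ncol(ts$data))
    if (n_discard > 0L) confounds <- confounds[-(seq_len(n_discard)), , drop = FALSE]
  }
  out <- discard_initial(ts, n_discard)
  out <- detrend_poly(out, detrend_order)
  out <- regress_confounds(out, confounds)
  out <- bandpass(out, low, high)
  if (global_signal) out <- global_signal_regress(out)
  attr(out, "prep") <- list(order = c("discard", "detrend", "confounds",
                                      "bandpass", if (global_signal) "gsr"),
                            n_discard = n_discard, detrend_order = detrend_order,
                            band = c(low, high), gsr = global_signal)
  out
}

#' Read a whitespace/TSV confound file
#'
#' One row per timepoint, one column per nuisance regressor, header row
#' expected. Columns are used as-is; an intercept is added by
#' [regress_confounds] itself.
#'
#' @param path file path.
#' @return Numeric matrix `T x Q`.
#' @export
read_confounds <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  as.matrix(df)
}
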
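#' Sliding-window specification
#'
#' Windows of `n_t` samples advance by `step` samples; the trailing remainder
#' that does not complete a window is dropped, so the number of windows is
#' `floor((T - n_t)/step) + 1`.
#'
#' @param T total number of timepoints.
#' @param n_t window length in samples (e.g. 83 TR for 60 s at TR = 0.72 s).
#' @param step window step in samples (e.g. 5 TR for 3.6 s).
#' @return An object of class `window_spec` with fields `length`, `step`,
#'   `starts` (1-based), `n_windows`, `t_total`.
#' @export
make_windows <- function(T, n_t, step = 5L) {
  T <- as.integer(T); n_t <- as.integer(n_t); step <- as.integer(step)
  if (n_t < 1L || n_t > T) stopf("window length %d must be in [1, T = %d]", n_t, T)
  if (step < 1L) stopf("step must be >= 1")
  n_w <- (T - n_t) %/% step + 1L
  structure(list(length = n_t, step = step,
                 starts = 1L + step * (seq_len(n_w) - 1L),
                 n_windows = n_w, t_total = T),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %d windows of %d samples, step %d, over T = %d\n",
              x$n_windows, x$length, x$step, x$t_total))
  invisible(x)
}

#' Convert a duration in seconds to a whole number of TRs
#'
#' Rounds to the nearest integer number of samples and reports the realized
#' duration (60 s at TR = 0.72 s realizes 83 TR = 59.76 s).
#'
#' @param seconds duration in seconds.
#' @param tr repetition time in seconds.
#' @param quiet suppress the realized-duration message.
#' @return integer number of samples.
#' @export
seconds_to_tr <- function(seconds, tr, quiet = TRUE) {
  n <- max(1L, as.integer(round(seconds / tr)))
  if (!quiet)
    message(sprintf("%g s -> %d TR (realized %.2f s at TR = %g s)",
                    seconds, n, n * tr, tr))
  n
}

#' Normalize a windowed data matrix
#'
#' Row-wise z-scoring followed by division by the square root of the window
#' length, so the implicit connectivity matrix `Xw %*% t(Xw)` has unit diagonal
#' and off-diagonal entries equal to Pearson correlations within the window.
#'
#' @param Xw numeric `N_V x N_T` windowed data matrix.
#' @return Normalized matrix: every row has mean 0 and unit Euclidean norm.
#' @export
normalize_window <- function(Xw) {
  Xw <- as.matrix(Xw)
  n_t <- ncol(Xw)
  m <- rowMeans(Xw)
  Xc <- Xw - m
  ## population-style scaling: z-scores divided by sqrt(window length)
  s <- sqrt(rowSums(Xc^2) / n_t)
  bad <- which(s == 0)
  if (length(bad))
    stopf("constant timecourse within window for voxel row(s): %s (degenerate correlation)",
          paste(head(bad, 5L), collapse = ", "))
  Xc / (s * sqrt(n_t))
}

#' Rank-M basis of the stationary connectivity matrix
#'
#' Top-M eigenpairs of the full-run connectivity `C = X %*% t(X)` (with `X`
#' normalized over the whole run by the same z-score + 1/sqrt(T) convention as
#' windows, so `C` is the stationary Pearson correlation matrix). Computed via
#' the `T x T` Gram matrix, so no `N_V x N_V` matrix is ever formed and the
#' result is deterministic.
#'
#' @param X normalized `N_V x T` matrix (see [normalize_window]).
#' @param M requested rank (default 50).
#' @param tol eigenvalues below `tol * max(eigenvalue)` are treated as
#'   numerically zero.
#' @return An object of class `stationary_basis` with fields `values`
#'   (nonnegative, non-increasing), `vectors` (`N_V x M`, orthonormal), `M`.
#' @export
stationary_basis <- function(X, M = 50L, tol = 1e-10) {
  X <- as.matrix(X)
  M <- as.integer(M)
  if (M < 0L) stopf("M must be >= 0")
  if (M == 0L)
    return(structure(list(values = numeric(0),
                          vectors = matrix(0, nrow(X), 0), M = 0L),
                     class = "stationary_basis"))
  if (M > min(dim(X))) stopf("M (%d) exceeds min(N_V, T) = %d", M, min(dim(X)))
  G <- crossprod(X)                       # T x T Gram matrix; XX^T shares its spectrum
  eg <- eigen(G, symmetric = TRUE)
  vals <- eg$values
  keep <- which(vals > tol * max(vals, 0))
  if (length(keep) < M) {
    warnf("requested rank M = %d but numerical rank is %d; returning %d eigenpairs",
          M, length(keep), length(keep))
    M <- length(keep)
  }
  sel <- seq_len(M)
  mu <- vals[sel]
  V <- X %*% eg$vectors[, sel, drop = FALSE]
  V <- sweep(V, 2L, sqrt(mu), "/")        # orthonormal left eigenvectors of XX^T
  structure(list(values = mu, vectors = V, M = M), class = "stationary_basis")
}

#' @export
print.stationary_basis <- function(x, ...) {
  cat(sprintf("<stationary_basis> rank %d over %d voxels; eigenvalues [%g .. %g]\n",
              x$M, nrow(x$vectors),
              if (x$M) max(x$values) else NA, if (x$M) min(x$values) else NA))
  invisible(x)
}

#' Centered connectivity operator applied to a vector
#'
#' Computes `(C_i - C_M) w = Xw (Xw' w) - sum_k mu_k v_k (v_k' w)` strictly
#' right-to-left with matrix-vector products only; the `N_V x N_V` windowed or
#' stationary connectivity matrix is never materialized.
#'
#' @param Xw normalized `N_V x N_T` window matrix.
#' @param basis a [stationary_basis] from the same subject's full run (rank 0
#'   for no centering).
#' @param w numeric vector of length `N_V`.
#' @return numeric vector of length `N_V`.
#' @export
centered_matvec <- function(Xw, basis, w) {
  if (length(w) != nrow(Xw)) stopf("w has length %d, expected %d", length(w), nrow(Xw))
  out <- Xw %*% crossprod(Xw, w)
  if (basis$M > 0L) {
    if (nrow(basis$vectors) != nrow(Xw)) stopf("basis voxel dimension mismatch")
    out <- out - basis$vectors %*% (basis$values * crossprod(basis$vectors, w))
  }
  as.vector(out)
}

#' Leading eigenpair of the centered windowed connectivity
#'
#' The dominant pattern of a window: the eigenvector of
#' `C_i - C_M = Xw Xw' - V diag(mu) V'` whose eigenvalue is largest in
#' magnitude (default) or algebraically largest. The default solver projects
#' the operator onto its column space `[Xw, V]` via a pivoted QR and solves the
#' small `(N_T + M)`-dimensional symmetric eigenproblem exactly — deterministic,
#' matrix-free in the `O(N_V^2)` sense, with memory `O(N_V (N_T + M))`. An
#' ARPACK (implicitly restarted Lanczos) route using only
#' [centered_matvec] products is available as `method = "arpack"`.
#'
#' @param Xw normalized window matrix (see [normalize_window]).
#' @param basis a [stationary_basis] (rank 0 disables centering).
#' @param eig_mode `"magnitude"` (largest `|lambda|`, default) or
#'   `"algebraic"` (largest lambda).
#' @param method `"projection"` (exact, deterministic; default) or `"arpack"`.
#' @param tol relative gap below which the top eigenpair is flagged
#'   near-degenerate; also the ARPACK convergence tolerance.
#' @param max_iter ARPACK iteration cap.
#' @return An object of class `dominant_pattern`: `u` (unit-norm voxel map),
#'   `lambda` (signed eigenvalue), `degenerate` flag, `window_index`,
#'   `subject_id`.
#' @export
dominant_pattern <- function(Xw, basis = NULL, eig_mode = c("magnitude", "algebraic"),
                             method = c("projection", "arpack"),
                             tol = 1e-8, max_iter = 5000L) {
  eig_mode <- match.arg(eig_mode)
  method <- match.arg(method)
  Xw <- as.matrix(Xw)
  if (is.null(basis))
    basis <- structure(list(values = numeric(0),
                            vectors = matrix(0, nrow(Xw), 0), M = 0L),
                       class = "stationary_basis")
  n_v <- nrow(Xw)
  if (method == "projection" || n_v <= 3L) {
    res <- eig_projection(Xw, basis, eig_mode, tol)
  } else {
    res <- eig_arpack(Xw, basis, eig_mode, tol, max_iter)
  }
  u <- res$u / sqrt(sum(res$u^2))
  structure(list(u = as.vector(u), lambda = res$lambda,
                 degenerate = res$degenerate,
                 window_index = NA_integer_, subject_id = NULL),
            class = "dominant_pattern")
}

## exact solver on the operator's column space: A = B D B' with B = [Xw, V];
## pivoted QR of B, then dense eigen of R D_p R' (small, symmetric)
eig_projection <- function(Xw, basis, eig_mode, tol) {
  B <- cbind(Xw, basis$vectors)
  D <- c(rep(1, ncol(Xw)), -basis$values)
  qb <- qr(B, LAPACK = TRUE)
  Rfull <- qr.R(qb)
  d <- abs(diag(Rfull))
  r <- max(1L, sum(d > max(d, .Machine$double.eps) * 1e-12))
  Q <- qr.Q(qb)[, seq_len(r), drop = FALSE]
  R <- Rfull[seq_len(r), , drop = FALSE]
  Dp <- D[qb$pivot]
  S <- R %*% (Dp * t(R))
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  pick <- pick_eig(es$values, eig_mode)
  u <- as.vector(Q %*% es$vectors[, pick$i])
  list(u = u, lambda = es$values[pick$i], degenerate = pick$gap < tol)
}

eig_arpack <- function(Xw, basis, eig_mode, tol, max_iter) {
  n_v <- nrow(Xw)
  f <- function(x, extra) centered_matvec(Xw, basis, x)
  which <- if (eig_mode == "magnitude") "LM" else "LA"
  start <- with_seed(271828L, rnorm(n_v))
  res <- igraph::arpack(f, sym = TRUE,
                        options = list(n = n_v, nev = 2L,
                                       ncv = min(n_v, 20L), which = which,
                                       maxiter = max_iter, tol = tol,
                                       start = start / sqrt(sum(start^2))))
  vals <- res$values
  pick <- pick_eig(vals, eig_mode)
  list(u = as.vector(res$vectors[, pick$i]), lambda = vals[pick$i],
       degenerate = pick$gap < tol)
}

## index of the selected eigenvalue plus the relative gap to the runner-up
pick_eig <- function(values, eig_mode) {
  key <- if (eig_mode == "magnitude") abs(values) else values
  ord <- order(key, decreasing = TRUE)
  i <- ord[1]
  gap <- if (length(values) > 1L) {
    (key[ord[1]] - key[ord[2]]) / max(abs(values[i]), .Machine$double.eps)
  } else Inf
  list(i = i, gap = gap)
}

#' Window-by-window dominant patterns for one subject
#'
#' Normalizes the full preprocessed run, builds the rank-M stationary basis,
#' then extracts each window's dominant pattern of the centered connectivity.
#' Signs are aligned across consecutive windows: each window's map is flipped,
#' if needed, to have nonnegative cosine with the previous one (the first
#' window is flipped so its maximum-magnitude voxel is positive) — sign is
#' physically irrelevant (`u u' = (-u)(-u)'`) but a deterministic convention
#' keeps outputs reproducible.
#'
#' @param ts preprocessed [voxel_ts].
#' @param spec a [window_spec] (or NULL to build one from `window_sec`,
#'   `step_sec` and the stored TR).
#' @param M stationary-centering rank (default 50; 0 disables centering).
#' @param window_sec,step_sec used when `spec` is NULL (defaults 60 s / 3.6 s).
#' @param eig_mode,method passed to [dominant_pattern].
#' @param verbose log progress every 50 windows.
#' @return An object of class `dominant_patterns`: `u` (`N_V x N_W` matrix,
#'   unit-norm columns), `lambda`, `degenerate`, `spec`, `M`, plus the mask
#'   geometry of the input.
#' @export
run_subject <- function(ts, spec = NULL, M = 50L, window_sec = 60, step_sec = 3.6,
                        eig_mode = "magnitude", method = "projection",
                        verbose = FALSE) {
  stopifnot(inherits(ts, "voxel_ts"))
  T <- ncol(ts$data)
  if (is.null(spec))
    spec <- make_windows(T, seconds_to_tr(window_sec, ts$tr),
                         seconds_to_tr(step_sec, ts$tr))
  if (spec$t_total != T) stopf("window spec was built for T = %d, data has T = %d",
                               spec$t_total, T)
  M <- min(as.integer(M), min(nrow(ts$data), T))
  Xfull <- normalize_window(ts$data)      # same convention, window = full run
  basis <- stationary_basis(Xfull, M)
  n_w <- spec$n_windows
  U <- matrix(0, nrow(ts$data), n_w)
  lam <- numeric(n_w)
  degen <- logical(n_w)
  prev <- NULL
  for (i in seq_len(n_w)) {
    s <- spec$starts[i]
    Xw <- normalize_window(ts$data[, s:(s + spec$length - 1L), drop = FALSE])
    dp <- tryCatch(
      dominant_pattern(Xw, basis, eig_mode = eig_mode, method = method),
      error = function(e) stopf("window %d: %s", i, conditionMessage(e)))
    u <- dp$u
    if (is.null(prev)) {
      if (u[which.max(abs(u))] < 0) u <- -u
    } else if (sum(u * prev) < 0) u <- -u
    U[, i] <- u
    lam[i] <- dp$lambda
    degen[i] <- dp$degenerate
    prev <- u
    if (verbose && i %% 50L == 0L)
      message(sprintf("  window %d / %d", i, n_w))
  }
  structure(list(u = U, lambda = lam, degenerate = degen, spec = spec,
                 M = basis$M, eig_mode = eig_mode,
                 mask_indices = ts$mask_indices, dim3 = ts$dim3,
                 affine = ts$affine, tr = ts$tr,
                 subject_id = ts$subject_id),
            class = "dominant_patterns")
}

#' @export
print.dominant_patterns <- function(x, ...) {
  cat(sprintf("<dominant_patterns> %d voxels x %d windows (N_T = %d, step = %d, M = %d)\n",
              nrow(x$u), ncol(x$u), x$spec$length, x$spec$step, x$M))
  invisible(x)
}
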
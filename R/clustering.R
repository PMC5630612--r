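#' Concatenate dominant patterns across subjects
#'
#' Stacks per-subject `N_V x N_W` dominant-pattern matrices column-wise into
#' the pooled matrix `U` (`N_V x N_W N_S`), subject-major / window-minor column
#' order. All subjects must share the same mask and voxel order.
#'
#' @param dp_list list of [run_subject] results (class `dominant_patterns`).
#' @return An object of class `pattern_pool`: `u` (pooled matrix), `subject`
#'   and `window` index per column, plus the shared mask geometry.
#' @export
concatenate_patterns <- function(dp_list) {
  if (!length(dp_list)) stopf("empty pattern list")
  ref <- dp_list[[1L]]
  for (i in seq_along(dp_list)) {
    d <- dp_list[[i]]
    if (!inherits(d, "dominant_patterns")) stopf("element %d is not a dominant_patterns", i)
    if (nrow(d$u) != nrow(ref$u) || !identical(d$mask_indices, ref$mask_indices))
      stopf("subject %s (element %d) has a different mask/voxel order",
            d$subject_id %||% i, i)
  }
  U <- do.call(cbind, lapply(dp_list, `[[`, "u"))
  subj <- rep(vapply(seq_along(dp_list),
                     function(i) as.character(dp_list[[i]]$subject_id %||% i), ""),
              vapply(dp_list, function(d) ncol(d$u), 0L))
  win <- unlist(lapply(dp_list, function(d) seq_len(ncol(d$u))))
  structure(list(u = U, subject = subj, window = win,
                 mask_indices = ref$mask_indices, dim3 = ref$dim3,
                 affine = ref$affine),
            class = "pattern_pool")
}

#' @export
print.pattern_pool <- function(x, ...) {
  cat(sprintf("<pattern_pool> %d voxels x %d patterns (%d subject(s))\n",
              nrow(x$u), ncol(x$u), length(unique(x$subject))))
  invisible(x)
}

## canonical sign: flip each column so its maximum-|value| entry is positive.
## Makes every downstream result exactly invariant to input sign flips.
canonicalize_signs <- function(U) {
  idx <- max.col(t(abs(U)), ties.method = "first")
  flip <- U[cbind(idx, seq_len(ncol(U)))] < 0
  U[, flip] <- -U[, flip, drop = FALSE]
  U
}

unit_columns <- function(U) {
  nrm <- sqrt(colSums(U^2))
  nrm[nrm == 0] <- 1
  sweep(U, 2L, nrm, "/")
}

## |cosine| similarity of unit columns of U against unit columns of R
abs_cos <- function(U, R) abs(crossprod(U, R))

## k-means++ seeding under the sign-invariant cosine distance d = 1 - |cos|
kmeanspp_init <- function(U, K) {
  n <- ncol(U)
  centers <- integer(K)
  centers[1L] <- sample.int(n, 1L)
  d <- 1 - as.vector(abs_cos(U, U[, centers[1L], drop = FALSE]))
  if (K > 1L) for (k in 2L:K) {
    p <- pmax(d, 0)
    if (sum(p) <= 0) p <- rep(1, n)
    centers[k] <- sample.int(n, 1L, prob = p)
    d <- pmin(d, 1 - as.vector(abs_cos(U, U[, centers[k], drop = FALSE])))
  }
  U[, centers, drop = FALSE]
}

#' Sign-invariant cosine k-means
#'
#' Clusters unit-norm spatial maps with distance `d(u, r) = 1 - |cos(u, r)|`,
#' so that a map and its negation are treated as the same pattern (inverting
#' the sign of an eigenvector leaves its rank-1 connectivity unchanged). Each
#' assignment flips the working sign of a column to agree with its centroid
#' before the centroid update; centroids are renormalized every iteration.
#' Input columns are first put in a canonical sign (maximum-magnitude entry
#' positive), so results are bitwise invariant to sign flips of the input.
#' The best of `n_init` k-means++ restarts is returned.
#'
#' @param U `N_V x n` matrix of patterns (columns), or a `pattern_pool`.
#' @param K number of clusters.
#' @param n_init number of restarts (default 20).
#' @param max_iter iteration cap per restart (default 300).
#' @param seed integer seed controlling initialization.
#' @return An object of class `rdp_set`: `centroids` (`N_V x K`, unit norm),
#'   `assignments` (cluster id per column), `occupancy`, `objective`
#'   (mean `1 - |cos|`), `K`, `seed`, `n_init`, plus column metadata and mask
#'   geometry when a `pattern_pool` was given.
#' @export
cosine_kmeans <- function(U, K, n_init = 20L, max_iter = 300L, seed = 1L) {
  pool <- NULL
  if (inherits(U, "pattern_pool")) { pool <- U; U <- pool$u }
  U <- as.matrix(U)
  n <- ncol(U)
  if (K < 1L) stopf("K must be >= 1")
  if (K > n) stopf("K (%d) exceeds number of patterns (%d)", K, n)
  U <- canonicalize_signs(unit_columns(U))

  best <- NULL
  with_seed(seed, {
    for (rep in seq_len(n_init)) {
      fit <- kmeans_once(U, K, max_iter)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
  })
  occ <- tabulate(best$assign, nbins = K) / n
  structure(list(centroids = best$centroids, assignments = best$assign,
                 occupancy = occ, objective = best$objective,
                 K = K, seed = seed, n_init = n_init,
                 subject = pool$subject, window = pool$window,
                 mask_indices = pool$mask_indices, dim3 = pool$dim3,
                 affine = pool$affine),
            class = "rdp_set")
}

kmeans_once <- function(U, K, max_iter) {
  R <- unit_columns(kmeanspp_init(U, K))
  n <- ncol(U)
  prev_obj <- Inf
  assign <- integer(n)
  for (it in seq_len(max_iter)) {
    S <- crossprod(U, R)                    # n x K signed cosine
    A <- abs(S)
    assign <- max.col(A, ties.method = "first")
    obj <- mean(1 - A[cbind(seq_len(n), assign)])
    ## objective is non-increasing by construction; tiny fp slack tolerated
    stopifnot(obj <= prev_obj + 1e-12)
    ## centroid update on sign-aligned members
    newR <- matrix(0, nrow(U), K)
    sgn <- sign(S[cbind(seq_len(n), assign)])
    sgn[sgn == 0] <- 1
    for (k in seq_len(K)) {
      mem <- which(assign == k)
      if (!length(mem)) {
        ## empty cluster: reseed from the worst-fit column
        worst <- which.min(A[cbind(seq_len(n), max.col(A, ties.method = "first"))])
        newR[, k] <- U[, worst]
        next
      }
      newR[, k] <- U[, mem, drop = FALSE] %*% sgn[mem]
    }
    newR <- unit_columns(newR)
    converged <- max(abs(newR - R)) < 1e-12
    R <- newR
    if (converged && obj >= prev_obj - 1e-12 && it > 1L) break
    prev_obj <- obj
  }
  ## final assignment against the converged centroids
  A <- abs_cos(U, R)
  assign <- max.col(A, ties.method = "first")
  obj <- mean(1 - A[cbind(seq_len(n), assign)])
  list(centroids = canonicalize_signs(R), assign = assign, objective = obj)
}

#' @export
print.rdp_set <- function(x, ...) {
  cat(sprintf("<rdp_set> K = %d RDPs over %d voxels; objective %.4g\n",
              x$K, nrow(x$centroids), x$objective))
  cat("  occupancy:", paste(sprintf("%.1f%%", 100 * x$occupancy), collapse = " "), "\n")
  invisible(x)
}

#' Cluster occupancy fractions
#'
#' Fraction of all (subject, window) pairs assigned to each cluster.
#'
#' @param assignments integer cluster ids (or an `rdp_set`).
#' @param K number of clusters (inferred when an `rdp_set` is given).
#' @return numeric vector of fractions summing to 1.
#' @export
occupancy <- function(assignments, K = NULL) {
  if (inherits(assignments, "rdp_set")) {
    K <- assignments$K
    assignments <- assignments$assignments
  }
  if (!length(assignments)) stopf("empty assignments")
  if (is.null(K)) K <- max(assignments)
  tabulate(assignments, nbins = K) / length(assignments)
}

#' Consensus selection of the number of RDPs
#'
#' For each candidate `K`, the pooled patterns are split into `folds` random
#' partitions (the same partition reused across all `K`); each fold in turn is
#' held out, clustering is fit on the rest, held-out columns are assigned to
#' their nearest centroid under `1 - |cos|`, and the consensus measure is the
#' worst-case (largest) per-cluster average held-out distance. The selected
#' `K` is the most parsimonious model whose consensus error is statistically
#' indistinguishable from the best: the smallest `K` whose fold-median is
#' within one fold standard error of the minimum median (or within `rel_tol`
#' relative slack, whichever is larger). This one-standard-error rule marks
#' the elbow where the error stops decreasing materially without being swayed
#' by noise-level fluctuations along the flat tail.
#'
#' @param U pattern matrix or `pattern_pool`.
#' @param K_range candidate cluster counts (default 1:30).
#' @param folds number of consensus folds (default 10).
#' @param n_init restarts per fold fit (default 5; the final model should be
#'   refit with more).
#' @param max_iter per-fit iteration cap.
#' @param rel_tol relative slack around the minimum median used by the
#'   one-standard-error selection rule (default 0.1).
#' @param seed integer seed (fold partition + initializations).
#' @return An object of class `consensus_curve`: `K_values`, `fold_values`
#'   (`folds x length(K_range)` matrix of worst-case average distances),
#'   `medians`, `selected_K`, `folds`, `seed`.
#' @export
consensus_select_K <- function(U, K_range = 1:30, folds = 10L, n_init = 5L,
                               max_iter = 100L, rel_tol = 0.1, seed = 1L) {
  if (inherits(U, "pattern_pool")) U <- U$u
  U <- canonicalize_signs(unit_columns(as.matrix(U)))
  n <- ncol(U)
  folds <- as.integer(folds)
  if (n < folds) stopf("need at least as many patterns (%d) as folds (%d)", n, folds)
  K_range <- sort(unique(as.integer(K_range)))
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  FV <- matrix(NA_real_, folds, length(K_range),
               dimnames = list(NULL, paste0("K", K_range)))
  for (ki in seq_along(K_range)) {
    K <- K_range[ki]
    for (f in seq_len(folds)) {
      train <- which(fold_id != f)
      test <- which(fold_id == f)
      if (length(train) < K) {
        warnf("fold %d has fewer training patterns (%d) than K = %d; skipped",
              f, length(train), K)
        next
      }
      fit <- cosine_kmeans(U[, train, drop = FALSE], K, n_init = n_init,
                           max_iter = max_iter,
                           seed = seed + 1000L * ki + f)
      A <- abs_cos(U[, test, drop = FALSE], fit$centroids)   # |cos| test x K
      a <- max.col(A, ties.method = "first")
      d <- 1 - A[cbind(seq_along(test), a)]
      percl <- vapply(seq_len(K), function(k) {
        m <- d[a == k]
        if (length(m)) mean(m) else NA_real_
      }, 0)
      FV[f, ki] <- max(percl, na.rm = TRUE)                  # worst-case cluster
    }
  }
  med <- apply(FV, 2L, median, na.rm = TRUE)
  ## one-standard-error rule: smallest K within max(fold SE, rel_tol) of the
  ## minimum median
  imin <- which.min(med)
  se <- sd(FV[, imin], na.rm = TRUE) / sqrt(sum(is.finite(FV[, imin])))
  thresh <- med[imin] + max(se, rel_tol * med[imin], 0)
  sel <- which(med <= thresh)[1L]
  structure(list(K_values = K_range, fold_values = FV, medians = unname(med),
                 selected_K = K_range[sel], folds = folds, seed = seed,
                 rel_tol = rel_tol),
            class = "consensus_curve")
}

#' @export
print.consensus_curve <- function(x, ...) {
  cat(sprintf("<consensus_curve> K in [%d, %d], %d folds; selected K = %d\n",
              min(x$K_values), max(x$K_values), x$folds, x$selected_K))
  invisible(x)
}
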
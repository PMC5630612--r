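# Independent oracles and small fixture builders shared across test files.
# Oracles are deliberately naive (dense, brute-force, enumeration) and never
# call the code paths they certify.

# dense centered connectivity matrix (the thing the package never builds)
dense_centered <- function(Xw, basis) {
  C <- tcrossprod(Xw)
  if (basis$M > 0)
    C <- C - basis$vectors %*% (basis$values * t(basis$vectors))
  C
}

# leading eigenpair of a dense symmetric matrix, by magnitude or algebraic
dense_leading <- function(C, mode = "magnitude") {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  i <- if (mode == "magnitude") which.max(abs(e$values)) else which.max(e$values)
  list(u = e$vectors[, i], lambda = e$values[i])
}

# a random voxel_ts on a trivial grid (no spatial structure needed)
random_ts <- function(n_v, T, tr = 0.72, seed = 1) {
  set.seed(seed)
  coords <- cbind(seq_len(n_v), 1L, 1L)
  voxel_ts(matrix(rnorm(n_v * T), n_v, T), coords, c(n_v, 1L, 1L),
           diag(4), tr)
}

# a label_volume built directly from coordinates + labels (for parcellation
# tests that do not need RDPs)
make_label_volume <- function(labels, coords, dim3, affine = NULL, K = NULL) {
  if (is.null(affine)) {
    affine <- diag(c(2, 2, 2, 1))
    affine[1:3, 4] <- -2 * (dim3 - 1) / 2   # world x = 0 midplane for even dims
  }
  structure(list(labels = as.integer(labels), K = K %||% max(1L, max(labels)),
                 mask_indices = as.matrix(coords), dim3 = as.integer(dim3),
                 affine = affine),
            class = "label_volume")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flood-fill connected components by breadth-first search (independent of the
# package's graph-based implementation)
bfs_components <- function(labels, coords, dim3, connectivity) {
  n <- nrow(coords)
  key <- function(p) paste(p[1], p[2], p[3])
  row_of <- new.env(hash = TRUE)
  for (i in seq_len(n)) assign(key(coords[i, ]), i, envir = row_of)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (o in seq_len(nrow(off))) {
        p <- coords[v, ] + off[o, ]
        if (any(p < 1) || any(p > dim3)) next
        j <- mget(key(p), envir = row_of, ifnotfound = list(NULL))[[1]]
        if (!is.null(j) && comp[j] == 0L && labels[j] == labels[v]) {
          comp[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

# best bijective matching of two centroid sets by exhaustive permutation
brute_force_match <- function(A, B) {
  M <- abs(cor(A, B))
  k <- min(dim(M))
  stopifnot(k <= 6)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  if (nrow(M) <= ncol(M)) {
    best <- -Inf
    for (p in perms(seq_len(ncol(M)))) {
      val <- sum(M[cbind(seq_len(nrow(M)), p[seq_len(nrow(M))])])
      best <- max(best, val)
    }
    best / nrow(M)
  } else {
    brute_force_match(B, A)
  }
}

# Rand index by explicit enumeration of all item pairs
ri_pairs <- function(x, y) {
  n <- length(x)
  agree <- 0L; total <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    total <- total + 1L
    same_x <- x[i] == x[j]; same_y <- y[i] == y[j]
    if (same_x == same_y) agree <- agree + 1L
  }
  agree / total
}

# shared mid-size simulation for cross-file reuse (built once per session)
.sim_cache <- new.env()
cached_sim <- function() {
  if (is.null(.sim_cache$sim))
    .sim_cache$sim <- simulate_dfc_dataset(n_subjects = 2, grid_dim = c(12, 12, 10),
                                           n_states = 2, T = 360, dwell = 20,
                                           snr = 4, seed = 303)
  .sim_cache$sim
}
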
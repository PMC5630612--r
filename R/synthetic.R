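#' Simulate multi-subject 4D fMRI data with switching network states
#'
#' Generates resting-state-like runs in which spatial covariance switches
#' between `n_states` planted patterns. Each pattern is a unit-norm voxel map
#' with constant magnitude and a piecewise-constant sign structure over cubic
#' cells (so the implied sign-code parcellation has contiguous regions), the
#' first pattern mirror-symmetric across the mid-sagittal plane, and all
#' patterns pairwise near-orthogonal (`|cos| < 0.2`). During an epoch in state
#' k, every voxel receives a shared band-limited latent timecourse weighted by
#' pattern k, plus i.i.d. Gaussian noise; `snr` is the per-voxel
#' signal-to-noise variance ratio. The state sequence is Markov: after each
#' dwell of `dwell` windows the state switches uniformly at random to one of
#' the other states.
#'
#' @param n_subjects number of subjects (runs).
#' @param grid_dim 3D grid dimensions (default `c(20, 20, 16)` at 2 mm
#'   isotropic, ellipsoidal mask of roughly 2-4k voxels).
#' @param n_states number of planted patterns / states (>= 2, unless
#'   `n_states = 1` for the noiseless single-state limit).
#' @param T timepoints per run (>= 120; default 864, ~10 min at TR 0.72 s).
#' @param tr repetition time in seconds (default 0.72).
#' @param dwell state dwell time in windows (default 30; one window advances
#'   by `step` samples, so an epoch lasts `dwell * step` samples).
#' @param step window step in samples used to convert `dwell` to samples
#'   (default 5 TR, matching the analysis default).
#' @param snr per-voxel signal-to-noise variance ratio (> 0; `Inf` for the
#'   noiseless limit).
#' @param cell cube edge (voxels) of the sign cells (default 4).
#' @param band latent-timecourse pass band in Hz (default `c(0.0167, 0.15)`,
#'   inside the preprocessing band so filtering preserves planted structure).
#' @param seed integer seed; generation is bit-reproducible.
#' @return An object of class `dfc_simulation`: `subjects` (list of 4D
#'   arrays), `mask` (3D array), `ground_truth` (class `ground_truth`:
#'   `patterns` `N_V x n_states`, `state` per-sample state id per subject,
#'   `labels` planted per-voxel sign-code labels, `mask_indices`, `dim3`,
#'   `affine`, `tr`, parameters).
#' @export
simulate_dfc_dataset <- function(n_subjects = 4L, grid_dim = c(20L, 20L, 16L),
                                 n_states = 3L, T = 864L, tr = 0.72,
                                 dwell = 30L, step = 5L, snr = 2,
                                 cell = 4L, band = c(0.0167, 0.15),
                                 seed = 1L) {
  if (n_states < 1L) stopf("n_states must be >= 1")
  if (T < 120L) stopf("T must be >= 120")
  if (!(snr > 0)) stopf("snr must be positive")
  grid_dim <- as.integer(grid_dim)
  if (grid_dim[1] %% 2L != 0L)
    stopf("first grid dimension must be even so hemispheres split at the midplane")

  ## 2 mm isotropic, world x = 0 on the mid-sagittal plane between columns
  vox_mm <- 2
  affine <- diag(c(vox_mm, vox_mm, vox_mm, 1))
  affine[1:3, 4] <- -vox_mm * (grid_dim - 1) / 2

  mask <- ellipsoid_mask(grid_dim)
  coords <- mask_coords(mask)
  n_v <- nrow(coords)
  if (n_v < 200L) stopf("mask has only %d voxels; need >= 200", n_v)
  if (n_v < 10L * n_states)
    stopf("fewer masked voxels (%d) than 10 x n_states: signals under-determined", n_v)

  out <- with_seed(seed, {
    P <- planted_patterns(coords, grid_dim, n_states, cell)
    epoch <- max(1L, as.integer(dwell) * as.integer(step))
    g <- sqrt(n_v)                       # pattern magnitude is 1/sqrt(n_v)
    amp <- if (is.finite(snr)) sqrt(snr) * g else g
    noise_sd <- if (is.finite(snr)) 1 else 0
    subjects <- vector("list", n_subjects)
    states <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      st <- markov_states(T, n_states, epoch)
      Z <- latent_timecourses(T, n_states, tr, band)
      sig <- matrix(0, n_v, T)
      for (k in seq_len(n_states)) {
        on <- st == k
        if (any(on)) sig[, on] <- amp * (P[, k] %o% Z[on, k])
      }
      dat <- sig + matrix(rnorm(n_v * T, sd = noise_sd), n_v, T)
      vol <- array(0, c(grid_dim, T))
      lin <- linear_index(coords, grid_dim)
      flat <- matrix(vol, prod(grid_dim), T)
      flat[lin, ] <- dat
      subjects[[s]] <- array(flat, c(grid_dim, T))
      states[[s]] <- st
    }
    list(subjects = subjects, states = states, P = P)
  })

  labels <- assign_labels(out$P, coords, grid_dim, affine)$labels
  gt <- structure(list(patterns = out$P, state = out$states, labels = labels,
                       mask_indices = coords, dim3 = grid_dim, affine = affine,
                       tr = tr, n_states = as.integer(n_states),
                       dwell = as.integer(dwell), step = as.integer(step),
                       snr = snr, seed = as.integer(seed)),
                  class = "ground_truth")
  structure(list(subjects = out$subjects, mask = mask, ground_truth = gt),
            class = "dfc_simulation")
}

#' @export
print.dfc_simulation <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf("<dfc_simulation> %d subject(s), grid %s, %d masked voxels, %d states, T = %d, snr = %g\n",
              length(x$subjects), paste(gt$dim3, collapse = "x"),
              nrow(gt$patterns), gt$n_states, dim(x$subjects[[1]])[4], gt$snr))
  invisible(x)
}

ellipsoid_mask <- function(grid_dim) {
  half <- (grid_dim - 1) / 2
  semi <- 0.95 * grid_dim / 2
  idx <- as.matrix(expand.grid(i = seq_len(grid_dim[1]),
                               j = seq_len(grid_dim[2]),
                               k = seq_len(grid_dim[3])))
  r2 <- ((idx[, 1] - 1 - half[1]) / semi[1])^2 +
        ((idx[, 2] - 1 - half[2]) / semi[2])^2 +
        ((idx[, 3] - 1 - half[3]) / semi[3])^2
  array(as.integer(r2 <= 1), grid_dim)
}

## Unit-norm constant-magnitude sign patterns, piecewise constant over
## cell^3 blocks; pattern 1 mirror-symmetric in i <-> nx+1-i; pairwise
## |cos| < 0.2 enforced by redraws. Each pattern's voxel sum is balanced to
## near zero (greedy cell flips) so the global signal carries essentially no
## planted component and global signal regression leaves the patterns intact.
planted_patterns <- function(coords, grid_dim, n_states, cell) {
  n_v <- nrow(coords)
  cell_id <- (coords[, 1] - 1L) %/% cell +
    1000L * ((coords[, 2] - 1L) %/% cell) +
    1000000L * ((coords[, 3] - 1L) %/% cell)
  mirror_i <- grid_dim[1] + 1L - coords[, 1]
  mirror_id <- (mirror_i - 1L) %/% cell +
    1000L * ((coords[, 2] - 1L) %/% cell) +
    1000000L * ((coords[, 3] - 1L) %/% cell)
  cells <- sort(unique(cell_id))
  ci <- match(cell_id, cells)
  mi <- match(mirror_id, cells)
  csize <- tabulate(ci, nbins = length(cells))

  ## cell index of each cell's mirror image
  mirror_cell <- vapply(seq_along(cells), function(cc) {
    v <- which(ci == cc)[1]; mi[v]
  }, 0L)

  ## greedily flip cell signs (mirror pairs jointly when symmetric) until the
  ## voxel-weighted sign sum is as close to zero as single flips allow
  balance <- function(s_cell, symmetric) {
    groups <- if (symmetric) {
      unique(lapply(seq_along(cells), function(cc) sort(unique(c(cc, mirror_cell[cc])))))
    } else as.list(seq_along(cells))
    gsize <- vapply(groups, function(g) sum(csize[g]), 0)
    repeat {
      tot <- sum(s_cell * csize)
      deltas <- vapply(seq_along(groups), function(gi)
        -2 * s_cell[groups[[gi]][1]] * gsize[gi], 0)
      best <- which.min(abs(tot + deltas))
      if (abs(tot + deltas[best]) >= abs(tot)) break
      s_cell[groups[[best]]] <- -s_cell[groups[[best]]]
    }
    s_cell
  }

  draw <- function(symmetric) {
    s_cell <- sample(c(-1, 1), length(cells), replace = TRUE)
    if (symmetric)                           # same sign for mirrored cells
      s_cell <- s_cell[pmin(seq_along(cells), mirror_cell)]
    s_cell <- balance(s_cell, symmetric)
    s_cell[ci]
  }
  P <- matrix(0, n_v, n_states)
  P[, 1] <- draw(symmetric = TRUE)
  if (n_states > 1L) for (k in 2L:n_states) {
    for (try in 1:200) {
      cand <- draw(symmetric = FALSE)
      cs <- abs(crossprod(P[, seq_len(k - 1L), drop = FALSE], cand)) / n_v
      if (all(cs < 0.2)) break
      if (try == 200) stopf("could not draw near-orthogonal pattern %d", k)
    }
    P[, k] <- cand
  }
  P / sqrt(n_v)
}

## piecewise-constant Markov state sequence: uniform switch to another state
## after each dwell epoch
markov_states <- function(T, n_states, epoch) {
  if (n_states == 1L) return(rep(1L, T))
  st <- integer(0)
  cur <- sample.int(n_states, 1L)
  while (length(st) < T) {
    st <- c(st, rep(cur, epoch))
    others <- setdiff(seq_len(n_states), cur)
    cur <- others[sample.int(length(others), 1L)]
  }
  st[seq_len(T)]
}

## unit-variance Gaussian timecourses band-limited to `band` Hz
latent_timecourses <- function(T, n_states, tr, band) {
  nyq <- 1 / (2 * tr)
  bf <- signal::butter(5, band / nyq, type = "pass")
  Z <- matrix(rnorm((T + 200L) * n_states), T + 200L, n_states)
  Z <- apply(Z, 2L, function(z) signal::filtfilt(bf, z))
  Z <- Z[101:(100 + T), , drop = FALSE]
  scale(Z)[, , drop = FALSE] * sqrt((T - 1) / T)  # exact unit population variance
}

#' Planted state id per analysis window
#'
#' Maps a per-sample ground-truth state sequence to one state per window (the
#' state at the window's center sample).
#'
#' @param gt a `ground_truth`.
#' @param spec a [window_spec].
#' @param subject subject index.
#' @return integer vector of length `spec$n_windows`.
#' @export
window_states <- function(gt, spec, subject = 1L) {
  st <- gt$state[[subject]]
  centers <- spec$starts + (spec$length %/% 2L)
  st[pmin(centers, length(st))]
}

#' Write a simulated dataset to disk
#'
#' Writes gzipped NIfTI-1 4D volumes (one per subject), the 3D mask, and the
#' ground truth as JSON (patterns as flat arrays over masked voxels in C-order
#' over the 3D grid).
#'
#' @param sim a `dfc_simulation`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "dfc_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt <- sim$ground_truth
  paths <- character(0)
  for (s in seq_along(sim$subjects)) {
    p <- file.path(dir, sprintf("sub-%02d_bold.nii.gz", s))
    img <- RNifti::asNifti(sim$subjects[[s]])
    img <- RNifti::`pixdim<-`(img, c(2, 2, 2, gt$tr))
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  pm <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(sim$mask), pm)
  pj <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(patterns = gt$patterns, state = gt$state, labels = gt$labels,
         mask_index_order = "C-order over the 3D grid (first axis fastest)",
         dim = gt$dim3, affine = gt$affine, tr = gt$tr,
         n_states = gt$n_states, dwell = gt$dwell, step = gt$step,
         snr = gt$snr, seed = gt$seed),
    pj, digits = NA, auto_unbox = TRUE)
  invisible(c(paths, pm, pj))
}
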
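#' Masked voxel-by-time data matrix
#'
#' Container for one subject's (or session's) gray-matter voxel timecourses.
#' Rows are masked voxels in C-order scan of the 3D grid (x fastest), columns
#' are timepoints. The voxel order is a fixed function of the mask so that maps
#' can be projected back into the volume unambiguously.
#'
#' @param data numeric matrix, `N_V x T` (voxels by timepoints).
#' @param mask_indices integer matrix `N_V x 3` of 1-based voxel grid
#'   coordinates (i, j, k), in the same row order as `data`.
#' @param dim3 integer length-3 grid dimensions.
#' @param affine 4x4 voxel-to-mm affine (0-based voxel indices map to world mm).
#' @param tr repetition time in seconds.
#' @param subject_id optional identifier carried through the pipeline.
#' @return An object of class `voxel_ts`.
#' @export
voxel_ts <- function(data, mask_indices, dim3, affine, tr, subject_id = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stopf("`data` must be a numeric matrix")
  if (nrow(mask_indices) != nrow(data))
    stopf("mask_indices rows (%d) must match data rows (%d)",
          nrow(mask_indices), nrow(data))
  if (ncol(data) < 1L) stopf("T must be positive")
  if (any(!is.finite(data))) stopf("`data` contains non-finite values")
  structure(
    list(data = data,
         mask_indices = as.matrix(mask_indices),
         dim3 = as.integer(dim3),
         affine = affine,
         tr = as.numeric(tr),
         subject_id = subject_id),
    class = "voxel_ts")
}

#' @export
print.voxel_ts <- function(x, ...) {
  cat(sprintf("<voxel_ts> %d voxels x %d timepoints, TR = %g s, grid %s\n",
              nrow(x$data), ncol(x$data), x$tr,
              paste(x$dim3, collapse = "x")))
  if (!is.null(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  invisible(x)
}

#' @export
dim.voxel_ts <- function(x) dim(x$data)

#' Extract masked voxel timecourses from a 4D volume
#'
#' Applies a 3D mask to a 4D array (or NIfTI image) and returns the voxel x
#' time matrix in C-order row order (first grid axis fastest). Voxels with zero
#' variance across time are dropped from the mask (with a message), since
#' degenerate timecourses have no defined correlation.
#'
#' @param img 4D numeric array or `niftiImage` (x, y, z, t).
#' @param mask 3D array or `niftiImage`; nonzero voxels are kept.
#' @param tr repetition time in seconds; if `img` is a NIfTI image with time
#'   units set, taken from the header when omitted.
#' @param affine 4x4 affine; taken from the NIfTI header when available.
#' @param subject_id optional identifier.
#' @param drop_constant drop voxels whose timecourse has zero variance
#'   (default TRUE).
#' @return A [voxel_ts].
#' @export
mask_timeseries <- function(img, mask, tr = NULL, affine = NULL,
                            subject_id = NULL, drop_constant = TRUE) {
  if (inherits(img, "niftiImage")) {
    if (is.null(affine)) affine <- structure(RNifti::xform(img), class = NULL)
    if (is.null(tr)) {
      pd <- RNifti::pixdim(img)
      if (length(pd) >= 4 && pd[4] > 0) tr <- pd[4]
    }
    img <- as.array(img)
  }
  if (inherits(mask, "niftiImage")) mask <- as.array(mask)
  if (length(dim(img)) != 4L) stopf("`img` must be 4D")
  if (!all(dim(img)[1:3] == dim(mask)))
    stopf("mask grid %s does not match image grid %s",
          paste(dim(mask), collapse = "x"), paste(dim(img)[1:3], collapse = "x"))
  if (is.null(affine)) affine <- diag(4)
  if (is.null(tr)) stopf("`tr` must be supplied when the image has no header")

  keep <- mask_coords(mask)
  flat <- matrix(img, prod(dim(img)[1:3]), dim(img)[4])
  lin <- linear_index(keep, dim(mask))
  dat <- flat[lin, , drop = FALSE]
  if (drop_constant) {
    v <- rowVars(dat)
    if (any(v == 0)) {
      message(sprintf("dropping %d zero-variance voxel(s) from the mask", sum(v == 0)))
      dat <- dat[v > 0, , drop = FALSE]
      keep <- keep[v > 0, , drop = FALSE]
    }
  }
  voxel_ts(dat, keep, dim(mask), affine, tr, subject_id)
}

## 1-based (i,j,k) coordinates of nonzero mask voxels, C-order over the grid
## (first axis fastest) -- this fixes the row order of every voxel map.
mask_coords <- function(mask) {
  idx <- which(mask != 0)
  arrayInd(idx, dim(mask))
}

linear_index <- function(coords, dim3) {
  (coords[, 3] - 1L) * dim3[1] * dim3[2] + (coords[, 2] - 1L) * dim3[1] + coords[, 1]
}

rowVars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1L)
}

## World-mm coordinates of voxel centers (affine applied to 0-based indices).
world_coords <- function(mask_indices, affine) {
  ijk1 <- cbind(mask_indices - 1L, 1)
  xyz <- ijk1 %*% t(affine)
  xyz[, 1:3, drop = FALSE]
}

#' Project a voxel map back into the 3D grid
#'
#' @param values numeric vector over masked voxels (row order of the mask).
#' @param mask_indices,dim3 mask geometry as stored in [voxel_ts].
#' @param background fill value outside the mask.
#' @return 3D array of dimension `dim3`.
#' @export
unmask <- function(values, mask_indices, dim3, background = NA_real_) {
  vol <- array(background, dim = dim3)
  vol[linear_index(mask_indices, dim3)] <- values
  vol
}
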
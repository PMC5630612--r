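#' Sign-code labels from an RDP set
#'
#' Encodes, for every voxel, the signs of its contributions to the K RDPs as a
#' K-bit integer: `label(n) = sum_k 2^(k-1) * (sign(r_k(n)) + 1)/2`. Voxels
#' behaving the same way across all dynamic patterns share a label; each label
#' is a long-range pattern (its voxels need not be contiguous). Exact zeros map
#' to bit 0 (treated as negative) — a measure-zero event given a deterministic
#' rule.
#'
#' @param rdps an `rdp_set` (or a bare `N_V x K` centroid matrix plus geometry
#'   arguments).
#' @param mask_indices,dim3,affine mask geometry; taken from the `rdp_set` when
#'   available.
#' @return An object of class `label_volume`: `labels` (integer per masked
#'   voxel, in `[0, 2^K - 1]`), `K`, and the mask geometry. Out-of-mask voxels
#'   are represented by `NA` when exported to a volume.
#' @export
assign_labels <- function(rdps, mask_indices = NULL, dim3 = NULL, affine = NULL) {
  if (inherits(rdps, "rdp_set")) {
    R <- rdps$centroids
    mask_indices <- mask_indices %||% rdps$mask_indices
    dim3 <- dim3 %||% rdps$dim3
    affine <- affine %||% rdps$affine
  } else R <- as.matrix(rdps)
  K <- ncol(R)
  if (K < 1L) stopf("need at least one RDP")
  if (K > 30L) stopf("K > 30 would overflow the integer label code")
  bits <- R > 0                            # sign(0) -> bit 0
  lab <- as.integer(bits %*% 2^(seq_len(K) - 1L))
  structure(list(labels = lab, K = K, mask_indices = mask_indices,
                 dim3 = dim3, affine = affine),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %d voxels, K = %d RDPs, %d distinct labels\n",
              length(x$labels), x$K, length(unique(x$labels))))
  invisible(x)
}

## neighbor offsets for 6- or 26-connectivity
conn_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
  else if (connectivity != 26L) stopf("connectivity must be 6 or 26")
  g
}

#' Split labels into contiguous regions
#'
#' Finds, per label, the maximal connected components of its voxels under the
#' chosen neighborhood (26-connectivity by default). Region ids are stable:
#' sorted by parent label, then by decreasing size (ties by smallest linear
#' voxel index).
#'
#' @param labels a [label_volume].
#' @param connectivity 26 (faces + edges + corners, default) or 6 (faces).
#' @return An object of class `parcellation`: `region_id` per masked voxel,
#'   `regions` (a tibble: region_id, parent_label, n_voxels,
#'   centroid_x/y/z_mm), `connectivity`, plus the mask geometry.
#' @export
connected_components <- function(labels, connectivity = 26L) {
  stopifnot(inherits(labels, "label_volume"))
  connectivity <- as.integer(connectivity)
  off <- conn_offsets(connectivity)
  coords <- labels$mask_indices
  dim3 <- labels$dim3
  n <- nrow(coords)
  lin <- linear_index(coords, dim3)
  ## map linear voxel index -> row in the mask, with the label stored alongside
  row_of <- integer(prod(dim3)); row_of[lin] <- seq_len(n)
  lab <- labels$labels

  ## edges between neighboring in-mask voxels that share a label
  from <- integer(0); to <- integer(0)
  for (o in seq_len(nrow(off))) {
    nb <- sweep(coords, 2L, off[o, ], "+")
    ok <- nb[, 1] >= 1L & nb[, 1] <= dim3[1] &
          nb[, 2] >= 1L & nb[, 2] <= dim3[2] &
          nb[, 3] >= 1L & nb[, 3] <= dim3[3]
    r2 <- integer(n)
    r2[ok] <- row_of[linear_index(nb[ok, , drop = FALSE], dim3)]
    keep <- ok & r2 > 0L & lab == lab[pmax(r2, 1L)] & seq_len(n) < r2
    from <- c(from, which(keep)); to <- c(to, r2[keep])
  }
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  comp <- igraph::components(g)$membership

  ## stable region ids: by parent label, then descending size, then first voxel
  sizes <- tabulate(comp)
  comp_lab <- lab[match(seq_along(sizes), comp)]
  first_vox <- vapply(seq_along(sizes), function(cc) min(lin[comp == cc]), 0)
  ord <- order(comp_lab, -sizes, first_vox)
  new_id <- integer(length(sizes)); new_id[ord] <- seq_along(sizes)
  region_id <- new_id[comp]

  xyz <- world_coords(coords, labels$affine)
  cent <- vapply(1:3, function(j)
    as.vector(tapply(xyz[, j], region_id, mean)), numeric(length(sizes)))
  cent <- matrix(cent, nrow = length(sizes), ncol = 3)
  regions <- tibble::tibble(
    region_id = seq_along(sizes),
    parent_label = comp_lab[ord],
    n_voxels = as.integer(sizes[ord]),
    centroid_x_mm = cent[, 1], centroid_y_mm = cent[, 2], centroid_z_mm = cent[, 3])
  structure(list(region_id = region_id, regions = regions,
                 connectivity = connectivity, K = labels$K,
                 labels = lab, mask_indices = coords, dim3 = dim3,
                 affine = labels$affine, min_size = 1L),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d regions (%d labels) over %d voxels; %d-connectivity, min size %d\n",
              nrow(x$regions), length(unique(x$regions$parent_label)),
              sum(x$region_id > 0L), x$connectivity, x$min_size))
  invisible(x)
}

#' Prune small regions
#'
#' Removes contiguous regions with fewer than `min_size` voxels; their voxels
#' become background (they are not merged into neighbors). Labels with no
#' surviving region disappear from the unique-label set. Idempotent.
#'
#' @param parc a [connected_components] result.
#' @param min_size minimum region size in voxels (default 20).
#' @return Pruned `parcellation`; pruned voxels have `region_id = 0` and
#'   `labels = NA`.
#' @export
prune_small <- function(parc, min_size = 20L) {
  stopifnot(inherits(parc, "parcellation"))
  min_size <- as.integer(min_size)
  if (min_size < 1L) stopf("min_size must be >= 1")
  keep <- parc$regions$n_voxels >= min_size
  kept <- parc$regions[keep, , drop = FALSE]
  old_id <- kept$region_id
  kept$region_id <- seq_len(nrow(kept))
  map <- integer(max(parc$regions$region_id, 1L))
  map[old_id] <- kept$region_id
  rid <- parc$region_id
  dropv <- rid > 0L & !(rid %in% old_id)
  rid[dropv] <- 0L
  rid[rid > 0L] <- map[rid[rid > 0L]]
  parc$region_id <- rid
  parc$regions <- kept
  parc$labels[dropv] <- NA_integer_
  parc$min_size <- max(parc$min_size, min_size)
  parc
}

#' Pairwise centroid distances within a long-range pattern
#'
#' Euclidean distances in mm between the centroids of all pairs of contiguous
#' regions carrying the same label — the degree of spatial distribution of a
#' long-range dFC pattern.
#'
#' @param parc a `parcellation`.
#' @param label parent label to analyze; `NULL` pools all pairs within every
#'   label (never across labels).
#' @return A list: `pairs` (tibble region_a, region_b, parent_label,
#'   distance_mm), `mean_mm`, `sd_mm`, `n_pairs`. Labels with fewer than two
#'   regions yield an empty result with `n_pairs = 0`.
#' @export
pattern_distances <- function(parc, label = NULL) {
  stopifnot(inherits(parc, "parcellation"))
  reg <- parc$regions
  labs <- if (is.null(label)) unique(reg$parent_label) else label
  pa <- pb <- integer(0); pl <- integer(0); dd <- numeric(0)
  for (L in labs) {
    r <- reg[reg$parent_label == L, , drop = FALSE]
    if (nrow(r) < 2L) next
    cm <- as.matrix(r[, c("centroid_x_mm", "centroid_y_mm", "centroid_z_mm")])
    D <- as.matrix(dist(cm))
    ij <- which(upper.tri(D), arr.ind = TRUE)
    pa <- c(pa, r$region_id[ij[, 1]]); pb <- c(pb, r$region_id[ij[, 2]])
    pl <- c(pl, rep(L, nrow(ij))); dd <- c(dd, D[ij])
  }
  list(pairs = tibble::tibble(region_a = pa, region_b = pb,
                              parent_label = pl, distance_mm = dd),
       mean_mm = if (length(dd)) mean(dd) else NA_real_,
       sd_mm = if (length(dd) > 1L) sd(dd) else if (length(dd)) 0 else NA_real_,
       n_pairs = length(dd))
}

#' Hemispheric symmetry of the long-range patterns
#'
#' For each label, counts voxels in the left (world x < 0) and right
#' (world x > 0) hemispheres and computes the symmetry index
#' `SI = (#L - #R) / ((#L + #R)/2)`, which is 0 for perfect balance and +/-2
#' for complete asymmetry. Voxels exactly on the midline (x = 0) are counted in
#' neither hemisphere.
#'
#' @param labels a [label_volume] (or a pruned `parcellation`).
#' @param si_threshold labels with `|SI|` at or below this value count as
#'   symmetric in the summary (default 1, the conventional cut).
#' @return An object of class `symmetry_report`: tibble with `label`,
#'   `n_left`, `n_right`, `si`, plus attribute `frac_symmetric` — the fraction
#'   of covered voxels carrying a label with `|SI| <= si_threshold`.
#' @export
symmetry_index <- function(labels, si_threshold = 1) {
  if (inherits(labels, "parcellation"))
    labels <- structure(list(labels = labels$labels, K = labels$K,
                             mask_indices = labels$mask_indices,
                             dim3 = labels$dim3, affine = labels$affine),
                        class = "label_volume")
  stopifnot(inherits(labels, "label_volume"))
  x_mm <- world_coords(labels$mask_indices, labels$affine)[, 1]
  ok <- !is.na(labels$labels)
  lab <- labels$labels[ok]; x_mm <- x_mm[ok]
  uls <- sort(unique(lab))
  nl <- vapply(uls, function(L) sum(lab == L & x_mm < 0), 0L)
  nr <- vapply(uls, function(L) sum(lab == L & x_mm > 0), 0L)
  tot <- nl + nr
  keep <- tot > 0L
  uls <- uls[keep]; nl <- nl[keep]; nr <- nr[keep]; tot <- tot[keep]
  si <- (nl - nr) / (tot / 2)
  covered <- vapply(uls, function(L) sum(lab == L), 0L)  # includes midline voxels
  frac <- sum(covered[abs(si) <= si_threshold]) / sum(covered)
  out <- tibble::tibble(label = uls, n_left = as.integer(nl),
                        n_right = as.integer(nr), si = si)
  structure(out, class = c("symmetry_report", class(out)),
            frac_symmetric = frac, si_threshold = si_threshold)
}
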
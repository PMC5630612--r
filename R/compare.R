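#' Match two RDP sets by spatial correlation
#'
#' Pairs the centroids of two RDP sets (bijectively on the smaller set) so the
#' total absolute Pearson spatial correlation is maximal (Hungarian
#' assignment), and reports the mean matched `|correlation|`. Sign flips and
#' reordering of either set leave the result unchanged.
#'
#' @param A,B `rdp_set` objects (or bare `N_V x K` centroid matrices) defined
#'   on the same mask and voxel order.
#' @return An object of class `match_result`: `pairs` (tibble: `a`, `b`,
#'   `abs_correlation`), `mean_correlation`.
#' @export
match_rdp_sets <- function(A, B) {
  ca <- centroids_of(A); cb <- centroids_of(B)
  if (nrow(ca$R) != nrow(cb$R)) stopf("RDP sets live on different voxel counts")
  if (!is.null(ca$mask) && !is.null(cb$mask) && !identical(ca$mask, cb$mask))
    stopf("RDP sets have different masks/voxel orders")
  M <- abs(cor(ca$R, cb$R))               # K_A x K_B absolute spatial correlation
  swap <- FALSE
  if (nrow(M) > ncol(M)) { M <- t(M); swap <- TRUE }
  sol <- clue::solve_LSAP(M, maximum = TRUE)
  i <- seq_len(nrow(M)); j <- as.integer(sol)
  vals <- M[cbind(i, j)]
  pairs <- if (swap) tibble::tibble(a = j, b = i, abs_correlation = vals)
           else tibble::tibble(a = i, b = j, abs_correlation = vals)
  pairs <- pairs[order(pairs$a), ]
  structure(list(pairs = pairs, mean_correlation = mean(vals)),
            class = "match_result")
}

centroids_of <- function(x) {
  if (inherits(x, "rdp_set")) list(R = x$centroids, mask = x$mask_indices)
  else list(R = as.matrix(x), mask = NULL)
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d matched pairs; mean |spatial correlation| = %.3f\n",
              nrow(x$pairs), x$mean_correlation))
  invisible(x)
}

#' Partition similarity: AMI, RI and ARI
#'
#' Agreement between two labelings of the same voxels. The Rand index is
#' pair-counting agreement; the adjusted Rand index subtracts its expectation
#' under the permutation (hypergeometric) model; the adjusted mutual
#' information subtracts the expected mutual information under the same model
#' and normalizes by the arithmetic mean of the two entropies.
#'
#' @param X,Y integer label vectors of equal length, or `label_volume`s on the
#'   same mask. Voxels labelled `NA` in either partition are dropped.
#' @return A list with `ami`, `ri`, `ari`.
#' @export
partition_similarity <- function(X, Y) {
  x <- labels_of(X); y <- labels_of(Y)
  if (length(x) != length(y)) stopf("partitions cover different voxel counts")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  N <- length(x)
  if (N < 2L) stopf("need at least 2 items")
  ct <- table(x, y)
  a <- rowSums(ct); b <- colSums(ct)
  if (length(a) == 1L || length(b) == 1L)
    warnf("degenerate single-label partition; similarity limits returned")

  choose2 <- function(v) v * (v - 1) / 2
  s_nij <- sum(choose2(ct)); s_a <- sum(choose2(a)); s_b <- sum(choose2(b))
  np <- choose2(N)
  ri <- (np + 2 * s_nij - s_a - s_b) / np
  exp_idx <- s_a * s_b / np
  denom <- (s_a + s_b) / 2 - exp_idx
  ari <- if (denom == 0) 1 else (s_nij - exp_idx) / denom

  p <- ct / N
  pa <- a / N; pb <- b / N
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
  hx <- -sum(pa * log(pa)); hy <- -sum(pb * log(pb))
  emi <- expected_mi(a, b, N)
  ami_den <- (hx + hy) / 2 - emi
  ami <- if (abs(ami_den) < 1e-15) 1 else (mi - emi) / ami_den
  list(ami = ami, ri = ri, ari = ari)
}

labels_of <- function(x) {
  if (inherits(x, "label_volume")) x$labels
  else if (inherits(x, "parcellation")) x$labels
  else as.vector(x)
}

## Expected mutual information under the permutation model (Vinh et al. 2010):
## sum over cells and feasible nij of nij/N log(N nij / (ai bj)) times the
## hypergeometric probability, computed in log space.
expected_mi <- function(a, b, N) {
  emi <- 0
  lgN <- lgamma(N + 1)
  for (ai in a) {
    for (bj in b) {
      lo <- max(1L, ai + bj - N)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      term <- nij / N * log(N * nij / (ai * bj))
      lp <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(N - ai + 1) + lgamma(N - bj + 1) -
        lgN - lgamma(nij + 1) - lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
        lgamma(N - ai - bj + nij + 1)
      emi <- emi + sum(term * exp(lp))
    }
  }
  emi
}

#' Inter-centroid cosine similarity
#'
#' Symmetric `K x K` matrix of absolute cosine similarities between RDP
#' centroids, unit diagonal.
#'
#' @param rdps an `rdp_set` or centroid matrix with `K >= 2` columns.
#' @return `K x K` numeric matrix of `|cos|`.
#' @export
intercluster_cosine <- function(rdps) {
  R <- centroids_of(rdps)$R
  if (ncol(R) < 2L) stopf("need at least 2 centroids")
  R <- unit_columns(R)
  S <- abs(crossprod(R))
  diag(S) <- 1
  S
}

#' Overlap of labels with a reference labeling
#'
#' For every (label, reference label) pair, the fraction of the label's voxels
#' falling inside that reference parcel: `|intersection| / |label|`. Background
#' (`NA`) reference voxels are excluded, so rows sum to at most 1.
#'
#' @param X a `label_volume` (or label vector) to evaluate.
#' @param reference a `label_volume` (or label vector) on the same grid.
#' @return A tibble with `label`, `reference_label`, `overlap`.
#' @export
label_overlap <- function(X, reference) {
  x <- labels_of(X); r <- labels_of(reference)
  if (length(x) != length(r)) stopf("labelings cover different voxel counts")
  keep_x <- !is.na(x)
  if (!any(keep_x & !is.na(r))) {
    warnf("labelings do not overlap; empty table returned")
    return(tibble::tibble(label = integer(0), reference_label = integer(0),
                          overlap = numeric(0)))
  }
  sizes <- table(x[keep_x])
  both <- keep_x & !is.na(r)
  ct <- table(x[both], r[both])
  out <- as.data.frame(ct, stringsAsFactors = FALSE)
  names(out) <- c("label", "reference_label", "n")
  out$overlap <- out$n / as.numeric(sizes[out$label])
  out <- out[out$n > 0, c("label", "reference_label", "overlap")]
  out$label <- utils::type.convert(out$label, as.is = TRUE)
  out$reference_label <- utils::type.convert(out$reference_label, as.is = TRUE)
  tibble::as_tibble(out[order(out$label, out$reference_label), ])
}
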
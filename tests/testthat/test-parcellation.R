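test_that("sign-code labels implement the K-bit encoding", {
  # K = 6, hand-computed codes
  R <- rbind(rep(1, 6),                      # all positive  -> 63
             rep(-1, 6),                     # all negative  -> 0
             c(1, rep(-1, 5)),               # only bit 1    -> 1
             c(-1, 1, -1, 1, -1, 1))         # bits 2,4,6    -> 2 + 8 + 32 = 42
  lv <- assign_labels(R, mask_indices = cbind(1:4, 1, 1), dim3 = c(4, 1, 1),
                      affine = diag(4))
  expect_equal(lv$labels, c(63L, 0L, 1L, 42L))
  # zeros map to bit 0
  expect_equal(assign_labels(rbind(c(0, 1)))$labels, 2L)
  # K bounds
  expect_error(assign_labels(matrix(1, 2, 31)), "overflow")
  expect_error(assign_labels(matrix(1, 2, 0)), "at least one")
  # sign-flip of a column permutes codes consistently (bit k toggles)
  R2 <- R; R2[, 3] <- -R2[, 3]
  lv2 <- assign_labels(R2, cbind(1:4, 1, 1), c(4, 1, 1), diag(4))
  expect_equal(lv2$labels, as.integer(bitwXor(lv$labels, 4L)))
})

test_that("connected components split labels into contiguous regions", {
  # two 2x2x2 cubes with the same label, separated by a gap
  co <- as.matrix(expand.grid(i = 1:2, j = 1:2, k = 1:2))
  co <- rbind(co, cbind(co[, 1] + 4L, co[, 2], co[, 3]))
  lv <- make_label_volume(rep(5L, 16), co, c(8, 4, 4))
  p <- connected_components(lv, 26)
  expect_equal(nrow(p$regions), 2L)
  expect_equal(p$regions$parent_label, c(5L, 5L))
  expect_equal(p$regions$n_voxels, c(8L, 8L))
  expect_equal(sort(unique(p$region_id)), 1:2)
  # diagonal-only touch: connected under 26, separate under 6
  co2 <- rbind(c(1, 1, 1), c(2, 2, 2))
  lv2 <- make_label_volume(c(1L, 1L), co2, c(3, 3, 3))
  expect_equal(nrow(connected_components(lv2, 26)$regions), 1L)
  expect_equal(nrow(connected_components(lv2, 6)$regions), 2L)
  expect_error(connected_components(lv2, 18), "connectivity")
  # centroid is the mean of world coordinates
  one <- make_label_volume(c(2L, 2L), rbind(c(1, 1, 1), c(2, 1, 1)), c(4, 4, 4))
  r <- connected_components(one)$regions
  xyz <- world_coords(rbind(c(1, 1, 1), c(2, 1, 1)), one$affine)
  expect_equal(unlist(r[1, 4:6], use.names = FALSE), colMeans(xyz))
})

test_that("components agree with a breadth-first flood fill on random labelings", {
  set.seed(40)
  dim3 <- c(7, 6, 5)
  co <- as.matrix(expand.grid(i = 1:7, j = 1:6, k = 1:5))
  keep <- sample(nrow(co), 140)
  co <- co[keep, , drop = FALSE]
  labs <- sample(0:3, 140, replace = TRUE)
  lv <- make_label_volume(labs, co, dim3)
  for (conn in c(26L, 6L)) {
    p <- connected_components(lv, conn)
    ref <- bfs_components(labs, co, dim3, conn)
    # same partition of voxels into regions (ids may differ)
    expect_equal(partition_similarity(p$region_id, ref)$ari, 1)
    expect_equal(nrow(p$regions), length(unique(ref)))
    # each region is label-pure
    expect_true(all(tapply(labs, p$region_id, function(v) length(unique(v))) == 1))
  }
})

test_that("pruning removes sub-threshold regions and is idempotent", {
  # region A: 20 voxels (kept at threshold 20); region B: 19 voxels (pruned)
  coA <- cbind(1:20, 1L, 1L)
  coB <- cbind(1:19, 3L, 1L)
  lv <- make_label_volume(c(rep(1L, 20), rep(1L, 19)), rbind(coA, coB),
                          c(20, 4, 1))
  p <- connected_components(lv, 6)
  expect_equal(nrow(p$regions), 2L)
  pr <- prune_small(p, 20)
  expect_equal(nrow(pr$regions), 1L)
  expect_equal(pr$regions$n_voxels, 20L)
  expect_equal(sum(pr$region_id == 0L), 19L)
  expect_true(all(is.na(pr$labels[pr$region_id == 0L])))
  # idempotent
  expect_equal(prune_small(pr, 20), pr)
  # equals a direct size filter on the unpruned table
  keep <- p$regions$n_voxels >= 20
  expect_equal(nrow(pr$regions), sum(keep))
  # min_size 1 keeps everything
  expect_equal(nrow(prune_small(p, 1)$regions), 2L)
  expect_error(prune_small(p, 0), "min_size")
})

test_that("pattern distances match hand-computed centroid geometry", {
  # two 1-voxel regions of one label, 15 voxels = 30 mm apart in x
  co <- rbind(c(1, 1, 1), c(16, 1, 1))
  lv <- make_label_volume(c(9L, 9L), co, c(20, 4, 4))
  p <- connected_components(lv, 6)
  d <- pattern_distances(p)
  expect_equal(d$n_pairs, 1L)
  expect_equal(d$mean_mm, 30)
  expect_equal(d$sd_mm, 0)
  # three collinear regions at 0 / 30 / 60 mm: pairwise 30, 60, 30 -> mean 40
  co3 <- rbind(c(1, 1, 1), c(16, 1, 1), c(31, 1, 1))
  lv3 <- make_label_volume(c(9L, 9L, 9L), co3, c(40, 4, 4))
  d3 <- pattern_distances(connected_components(lv3, 6))
  expect_equal(d3$n_pairs, 3L)
  expect_equal(sort(d3$pairs$distance_mm), c(30, 30, 60))
  expect_equal(d3$mean_mm, 40)
  # pairs never cross labels; single-region labels yield no pairs
  co4 <- rbind(co3, c(1, 3, 1))
  lv4 <- make_label_volume(c(9L, 9L, 9L, 5L), co4, c(40, 4, 4))
  d4 <- pattern_distances(connected_components(lv4, 6))
  expect_equal(d4$n_pairs, 3L)
  expect_equal(pattern_distances(connected_components(lv4, 6), label = 5)$n_pairs, 0L)
  # brute-force oracle on a random parcellation
  set.seed(41)
  co5 <- as.matrix(expand.grid(1:6, 1:5, 1:4))
  lab5 <- sample(1:2, nrow(co5), replace = TRUE)
  p5 <- connected_components(make_label_volume(lab5, co5, c(6, 5, 4)), 26)
  d5 <- pattern_distances(p5)
  reg <- p5$regions
  brute <- numeric(0)
  for (L in unique(reg$parent_label)) {
    r <- reg[reg$parent_label == L, ]
    if (nrow(r) < 2) next
    for (i in seq_len(nrow(r) - 1)) for (j in (i + 1):nrow(r))
      brute <- c(brute, sqrt(sum((unlist(r[i, 4:6]) - unlist(r[j, 4:6]))^2)))
  }
  expect_equal(sort(d5$pairs$distance_mm), sort(brute))
})

test_that("symmetry index matches its closed form", {
  dim3 <- c(6, 4, 4)                         # world x = 0 between columns 3 and 4
  co <- rbind(c(1, 1, 1), c(6, 1, 1),        # label 1: one left + one right
              c(2, 2, 1),                    # label 2: left only
              c(5, 3, 1),                    # label 3: right only
              c(1, 4, 2), c(2, 4, 2), c(3, 4, 2), c(6, 4, 2))  # label 4: 3L + 1R
  lv <- make_label_volume(c(1L, 1L, 2L, 3L, 4L, 4L, 4L, 4L), co, dim3)
  rep_ <- symmetry_index(lv)
  expect_equal(rep_$si[rep_$label == 1], 0)
  expect_equal(rep_$si[rep_$label == 2], 2)
  expect_equal(rep_$si[rep_$label == 3], -2)
  expect_equal(rep_$si[rep_$label == 4], 1)
  expect_equal(rep_$n_left[rep_$label == 4], 3L)
  # frac_symmetric: labels 1 and 4 (|SI| <= 1) cover 6 of 8 voxels
  expect_equal(attr(rep_, "frac_symmetric"), 6 / 8)
  # mirror-symmetric sign pattern yields SI = 0 end-to-end
  sim <- cached_sim()
  gt <- sim$ground_truth
  lv1 <- assign_labels(gt$patterns[, 1, drop = FALSE], gt$mask_indices,
                       gt$dim3, gt$affine)
  si1 <- symmetry_index(lv1)
  expect_equal(si1$si, c(0, 0))
  expect_equal(attr(si1, "frac_symmetric"), 1)
})
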
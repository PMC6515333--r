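test_that("two homogeneous halves segment into the two halves", {
  img <- cbind(matrix(0.2, 64, 32), matrix(0.8, 64, 32))
  sv <- supervoxel_segment(img, M = 2)
  expect_equal(length(sv$stats), 2L)
  # label map is a partition
  expect_equal(sum(tabulate(sv$labels)), 64 * 64)
  # away from the boundary (beyond the patch half-width) the split is exact
  left <- sv$labels[, 1:27]; right <- sv$labels[, 38:64]
  expect_equal(length(unique(as.vector(left))), 1L)
  expect_equal(length(unique(as.vector(right))), 1L)
  expect_false(left[1, 1] == right[1, 1])
  expect_error(supervoxel_segment(img, M = 1), "M")
  expect_error(supervoxel_segment(img, M = 1e6), "M")
})

test_that("segmentation labels form 4-connected regions", {
  sl <- make_slice(phantom_params(image_size = c(96, 96), lv_center = c(52, 48),
                                  r_endo = 7, r_epi = 12, seed = 2))
  sv <- supervoxel_segment(sl$image, 150)
  lab <- sv$labels
  for (k in sample(unique(as.vector(lab)), 20)) {
    mask <- lab == k
    # flood fill from the first pixel must reach every pixel of the region
    comp <- matrix(FALSE, nrow(lab), ncol(lab))
    start <- which(mask, arr.ind = TRUE)[1, ]
    stack <- list(start)
    comp[start[1], start[2]] <- TRUE
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nrow(lab) && q[2] >= 1 && q[2] <= ncol(lab) &&
            mask[q[1], q[2]] && !comp[q[1], q[2]]) {
          comp[q[1], q[2]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    expect_equal(sum(comp), sum(mask))
  }
})

test_that("region adjacency matches a brute-force border scan", {
  # checkerboard: four regions, four edges, no diagonal adjacency
  cb <- rbind(c(1L, 2L), c(3L, 4L))
  adj <- region_adjacency(cb)
  expect_equal(adj, matrix(c(1L, 1L, 2L, 3L, 2L, 3L, 4L, 4L), ncol = 2,
                           dimnames = list(NULL, c("a", "b"))))
  expect_equal(nrow(region_adjacency(matrix(1L, 5, 5))), 0L)
  set.seed(10)
  for (rep in 1:10) {
    lab <- matrix(sample(1:6, 32 * 32, replace = TRUE), 32)
    got <- region_adjacency(lab)
    want <- matrix(integer(), 0, 2)
    for (r in 1:32) for (cc in 1:32) {
      for (d in list(c(1, 0), c(0, 1))) {
        r2 <- r + d[1]; c2 <- cc + d[2]
        if (r2 <= 32 && c2 <= 32 && lab[r, cc] != lab[r2, c2])
          want <- rbind(want, c(min(lab[r, cc], lab[r2, c2]),
                                max(lab[r, cc], lab[r2, c2])))
      }
    }
    want <- unique(want)
    want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
    expect_equal(unname(got), unname(want))
  }
})

test_that("hierarchical merging is exact, deterministic and matches the greedy oracle", {
  sl <- make_slice(phantom_params(image_size = c(96, 96), lv_center = c(52, 48),
                                  r_endo = 7, r_epi = 12, seed = 3))
  sv <- supervoxel_segment(sl$image, 120)
  L <- length(sv$stats)
  expect_identical(hierarchical_merge(sv, L), sv)
  one <- hierarchical_merge(sv, 1)
  expect_equal(length(one$stats), 1L)
  expect_equal(sum(one$labels == 1L), 96 * 96)
  # first merged pair equals the exhaustive arg-max adjacent pair
  merged <- hierarchical_merge(sv, L - 1L)
  cfg <- sv$cfg
  alpha <- 2 * (L - 1L) / length(sv$image)
  sims <- apply(sv$adjacency, 1, function(e)
    hybrid_similarity(sv$stats[[e[1]]], sv$stats[[e[2]]], cfg, "region",
                      alpha = alpha))
  best <- sv$adjacency[which.max(sims), ]
  # the two oracle regions share one label after the merge
  la <- merged$labels[sv$labels == best[1]]
  lb <- merged$labels[sv$labels == best[2]]
  expect_equal(unique(c(la, lb)), unique(la))
  # partition and pixel count preserved at every step
  mid <- hierarchical_merge(sv, max(2L, L %/% 2L))
  expect_equal(sum(tabulate(mid$labels)), 96 * 96)
  expect_equal(length(mid$stats), max(2L, L %/% 2L))
  # determinism
  expect_identical(hierarchical_merge(sv, 20)$labels,
                   hierarchical_merge(sv, 20)$labels)
  expect_error(hierarchical_merge(sv, 0), "K")
})

test_that("increasing M does not decrease boundary recall on the phantom annulus", {
  sl <- make_slice(phantom_params(image_size = c(128, 128),
                                  lv_center = c(70, 64), seed = 2))
  p <- sl$params
  xs <- matrix(rep(seq_len(128) - 0.5, each = 128), 128)
  ys <- matrix(rep(seq_len(128) - 0.5, 128), 128)
  d <- sqrt((xs - p$lv_center[1])^2 + (ys - p$lv_center[2])^2)
  annulus_edge <- abs(d - p$r_epi) < 0.7
  recall <- vapply(c(50, 200, 500), function(M) {
    lab <- supervoxel_segment(sl$image, M)$labels
    bd <- matrix(FALSE, 128, 128)
    dv <- lab[-128, ] != lab[-1, ]; dh <- lab[, -128] != lab[, -1]
    bd[-128, ][dv] <- TRUE; bd[-1, ][dv] <- TRUE
    bd[, -128][dh] <- TRUE; bd[, -1][dh] <- TRUE
    for (s in 1:2)
      bd <- bd | rbind(bd[-1, ], FALSE) | rbind(FALSE, bd[-128, ]) |
        cbind(bd[, -1], FALSE) | cbind(FALSE, bd[, -128])
    mean(bd[annulus_edge])
  }, 0)
  expect_true(all(diff(recall) >= 0))
})

test_that("proposal filters implement their stated semantics", {
  lab <- matrix(2L, 40, 40)
  lab[1:10, 1:10] <- 1L   # region touching the border
  lab[20:29, 20:29] <- 3L # interior 10x10 square
  img <- matrix(0.5, 40, 40); img[lab == 1L] <- 0.9; img[lab == 3L] <- 0.1
  sv <- structure(list(labels = lab, stats = region_stats(img, lab),
                       adjacency = region_adjacency(lab), image = img,
                       pc = img * 0, cfg = similarity_config(alpha = 0)),
                  class = "supervoxels")
  loose <- proposals_from_regions(sv, proposal_filter(area_range = c(0, 1),
                                                      border_margin = 0))
  expect_true(any(loose$region_a == 1 & is.na(loose$region_b)))
  strict <- proposals_from_regions(sv, proposal_filter(area_range = c(0, 1),
                                                       border_margin = 5))
  expect_false(any(strict$region_a == 1 & is.na(strict$region_b)))
  sq <- loose[loose$region_a == 3 & is.na(loose$region_b), ][1, ]
  expect_equal(sq$width, 10)
  expect_equal(sq$height, 10)
  # counting bound: singles + pair unions + star unions
  L <- length(sv$stats); E <- nrow(sv$adjacency)
  expect_lte(nrow(loose), 2 * L + E)
})

test_that("default phantom proposals cover the ground truth", {
  sl <- make_slice(phantom_params(seed = 12))
  pr <- propose_regions(sl$image, myo_config(tau = 24))
  expect_gt(max(iou(pr[, 1:4], as.numeric(sl$gt))), 0.5)
  expect_true(all(pr$width > 0 & pr$height > 0))
})
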
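test_that("erosion radius switches on the region-area threshold", {
  big <- matrix(0L, 80, 80)
  d2 <- outer((1:80 - 40)^2, (1:80 - 40)^2, "+")
  big[d2 <= 30^2] <- 1L                      # area ~ 2827 > 1000 -> r = 12
  e <- erode_region(big, erosion_policy())
  expect_identical(e, erode_oracle(big, 12L))
  # erosion of a disk by a disk is the shrunken disk
  expect_true(all(e[d2 <= 17^2] == 1L))
  expect_true(all(e[d2 > 19^2] == 0L))

  small <- matrix(0L, 40, 40)
  small[6:35, 6:35] <- 1L                    # area 900 <= 1000 -> r = 1
  expect_identical(erode_region(small, erosion_policy()),
                   erode_oracle(small, 1L))

  one <- matrix(0L, 9, 9); one[5, 5] <- 1L
  expect_identical(sum(erode_region(one, erosion_policy())), 0L)
})

test_that("erosion equals the brute-force offset oracle on random blobs", {
  set.seed(41)
  pol <- erosion_policy()
  for (k in 1:12) {
    blob <- mk_blob()
    r <- if (sum(blob) > pol$area_threshold) pol$large_radius else pol$small_radius
    expect_identical(erode_region(blob, pol), erode_oracle(blob, r))
  }
})

test_that("boundary seeds lie on the eroded boundary and sample deterministically", {
  set.seed(17)
  blob <- mk_blob()
  er <- erode_region(blob, erosion_policy())
  b <- rwcontour:::region_boundary(er)
  s1 <- sample_boundary_seeds(er, "lungs", count_ratio = 0.2, rng_seed = 7)
  expect_true(all(b[cbind(s1$row, s1$col)] == 1))
  expect_identical(s1, sample_boundary_seeds(er, "lungs", 0.2, rng_seed = 7))
  s2 <- sample_boundary_seeds(er, "lungs", 0.2, rng_seed = 8)
  expect_false(identical(s1, s2))
  # ratio 1 returns every boundary pixel
  all_b <- sample_boundary_seeds(er, "lungs", 1, 1, max_count = Inf)
  expect_identical(nrow(all_b), sum(b))
  # empty mask signals the fallback with an empty frame
  expect_identical(nrow(sample_boundary_seeds(matrix(0L, 5, 5), "lungs")), 0L)
})

test_that("the skeleton of a bar is its midline and stays inside the mask", {
  bar <- matrix(0L, 9, 30); bar[4:6, 3:28] <- 1L
  sk <- skeletonize(bar)
  pts <- which(sk == 1L, arr.ind = TRUE)
  expect_true(all(pts[, 1] == 5))            # midline row
  expect_gte(nrow(pts), 20)                  # spans most of the bar
  expect_true(all(bar[pts] == 1L))           # subset of the mask
  set.seed(2)
  for (k in 1:8) {
    blob <- mk_blob()
    sk <- skeletonize(blob)
    expect_true(all(blob[sk == 1L] == 1L))
  }
})

test_that("pruning removes short spurs but keeps short isolated lines", {
  sk <- matrix(0L, 15, 30)
  sk[8, 3:27] <- 1L                          # main line
  sk[5:7, 10] <- 1L                          # 3-px spur into the line
  pr <- prune_skeleton(sk, min_branch = 5L)
  # spur removed up to (at most) the branch pixel adjacent to the junction
  expect_identical(sum(pr[5:6, 10]), 0L)
  expect_lte(sum(pr[5:7, 10]), 1L)
  expect_gte(sum(pr[8, ]), 20L)              # main line intact
  short <- matrix(0L, 9, 9); short[5, 4:6] <- 1L
  expect_identical(prune_skeleton(short, 5L), short)
})

test_that("skeleton seeds handle degenerate masks and are deterministic", {
  one <- matrix(0L, 9, 9); one[4, 6] <- 1L
  s <- skeleton_seeds(one, "body", rng_seed = 1)
  expect_identical(c(s$row, s$col), c(4L, 6L))
  empty <- skeleton_seeds(matrix(0L, 5, 5), "body")
  expect_identical(nrow(empty), 0L)
  expect_true(isTRUE(attr(empty, "vanished")))
  blob <- mk_blob()
  expect_identical(skeleton_seeds(blob, "body", rng_seed = 3),
                   skeleton_seeds(blob, "body", rng_seed = 3))
})

test_that("the grey-level filter keeps exactly the predicate-satisfying seeds", {
  gray <- matrix(0L, 6, 6)
  gray[1, ] <- 5L; gray[2, ] <- 3L; gray[3, ] <- 255L; gray[4, ] <- 120L
  seeds <- data.frame(row = c(1, 2, 3, 4, 1, 4),
                      col = c(1, 2, 3, 4, 5, 6),
                      label = c("lungs", "body", "spinal_cord", "heart",
                                "airway", "gtv"))
  out <- filter_bad_seeds(seeds, gray)
  # lung at grey 5 kept; body at grey 3 removed; cord at 255 removed;
  # heart/gtv at 120 kept; airway at 5 kept
  expect_identical(out$label, c("lungs", "heart", "airway", "gtv"))
  expect_identical(attr(out, "starved"), c("body", "spinal_cord"))
  # idempotent
  again <- filter_bad_seeds(out, gray)
  expect_identical(again$label, out$label)
  expect_identical(attr(again, "starved"), character())
})

test_that("propagation seeds every surviving component and reports vanished ones", {
  ph <- shared_phantom()
  s0 <- ph$initial_slice
  gray <- window_soft_tissue(ph$volume$voxels[s0, , ])
  lm <- ph$truth[s0, , ]
  # identical consecutive geometry: every propagated seed passes the filter
  seeds <- propagate_seeds(lm, gray, rng_seed = 5, slice_index = s0)
  expect_gt(nrow(seeds), 0)
  expect_identical(attr(seeds, "starved"), character())
  for (lab in unique(seeds$label)) {
    sub <- seeds[seeds$label == lab, ]
    # seeds lie inside their own category's source region
    expect_true(all(lm[cbind(sub$row, sub$col)] ==
                      rwcontour:::category_code(lab)))
  }
  expect_identical(seeds, propagate_seeds(lm, gray, rng_seed = 5,
                                          slice_index = s0))
  # all-background previous slice: nothing to propagate
  none <- propagate_seeds(matrix(rw_background_code(), 20, 20),
                          matrix(0L, 20, 20))
  expect_identical(nrow(none), 0L)
})

test_that("a two-pixel-thin region survives through the skeleton source", {
  ph <- shared_phantom()
  s0 <- ph$initial_slice
  body <- rwcontour:::as_mask_labels(ph$truth[s0, , ] ==
                                       rwcontour:::category_code("body"))
  sizes <- tabulate(body[body > 0])
  thin_comp <- body == which.min(sizes)       # the chest-wall muscle sheet
  expect_lt(sum(thin_comp), 1000)
  # pure erosion annihilates it ...
  expect_identical(sum(erode_region(thin_comp, erosion_policy())), 0L)
  # ... but the skeleton still yields interior seeds
  sk <- skeleton_seeds(thin_comp, "body", rng_seed = 1)
  expect_gte(nrow(sk), 1)
  expect_true(all(thin_comp[cbind(sk$row, sk$col)] == 1))
})
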
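test_that("phantom tissues respect the anatomical HU table", {
  ph <- shared_phantom()
  hu <- ph$volume$voxels
  lungs <- hu[ph$truth == rwcontour:::category_code("lungs")]
  expect_gte(mean(lungs), -600)
  expect_lte(mean(lungs), -400)
  outside <- hu[ph$truth == rw_background_code()]
  expect_lt(abs(mean(outside) + 1000), 5)
  cord <- hu[ph$truth == rwcontour:::category_code("spinal_cord")]
  expect_gte(mean(cord), 20); expect_lte(mean(cord), 40)
  gtv <- hu[ph$truth == rwcontour:::category_code("gtv")]
  expect_gte(mean(gtv), 20); expect_lte(mean(gtv), 40)
})

test_that("phantom generation is deterministic under its seed", {
  a <- phantom_generate(phantom_spec(shape = c(20, 96, 96), rng_seed = 4))
  b <- phantom_generate(phantom_spec(shape = c(20, 96, 96), rng_seed = 4))
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$truth, b$truth)
  expect_identical(a$seeds, b$seeds)
  c <- phantom_generate(phantom_spec(shape = c(20, 96, 96), rng_seed = 5))
  expect_false(identical(a$volume$voxels, c$volume$voxels))
})

test_that("ground truth partitions the volume and obeys the stated anatomy", {
  ph <- shared_phantom()
  expect_true(all(ph$truth %in% seq_along(rw_categories())))
  hr <- ph$config$heart_range
  heart_slices <- which(apply(ph$truth == rwcontour:::category_code("heart"),
                              1, any))
  expect_gte(min(heart_slices), hr[1])
  expect_lte(max(heart_slices), hr[2])
  aw <- rwcontour:::category_code("airway")
  for (s in seq_len(dim(ph$truth)[1])) {
    m <- ph$truth[s, , ] == aw
    if (!any(m)) next
    ncomp <- max(rwcontour:::as_mask_labels(m))
    expect_identical(ncomp,
                     if (s >= ph$config$junction_slice) 1L else 2L)
  }
})

test_that("windowed grey levels satisfy the knowledge predicates almost surely", {
  ph <- shared_phantom()
  tab <- hu_knowledge_table()
  gray <- window_soft_tissue(ph$volume$voxels)
  for (cat in setdiff(rw_categories(), "background")) {
    g <- gray[ph$truth == rwcontour:::category_code(cat)]
    expect_gte(mean(tab[[cat]](g)), 0.99)
  }
})

test_that("initial seeds sit strictly inside their true organs", {
  ph <- shared_phantom()
  tr <- ph$truth[ph$initial_slice, , ]
  for (i in seq_len(nrow(ph$seeds))) {
    expect_identical(tr[ph$seeds$row[i], ph$seeds$col[i]],
                     rwcontour:::category_code(ph$seeds$label[i]))
  }
  counts <- table(ph$seeds$label)
  expect_true(all(counts >= 1 & counts <= 20))
  expect_identical(unname(counts[["spinal_cord"]]), 1L)  # one cord seed suffices
})

test_that("degradation is the identity at zero and weakens edges monotonically", {
  ph <- phantom_generate(phantom_spec(shape = c(16, 96, 96)))
  same <- phantom_degrade(ph, weak_edge_sigma = 0, noise_sigma = 0)
  expect_identical(same$volume$voxels, ph$volume$voxels)
  expect_identical(same$truth, ph$truth)
  grad <- function(v, s) {
    g <- window_soft_tissue(v[s, , ])
    b <- rwcontour:::region_boundary(ph$truth[s, , ] ==
                                       rwcontour:::category_code("lungs"))
    mean(sobel_magnitude(g)[b == 1L])
  }
  s <- 8L
  g0 <- grad(ph$volume$voxels, s)
  g1 <- grad(phantom_degrade(ph, 1, 0)$volume$voxels, s)
  g2 <- grad(phantom_degrade(ph, 2.5, 0)$volume$voxels, s)
  expect_gt(g0, g1)
  expect_gt(g1, g2)
})

test_that("phantom export writes volume, truth, seeds and config", {
  ph <- phantom_generate(phantom_spec(shape = c(16, 64, 64)))
  dir <- file.path(tempdir(), "ph_out")
  phantom_write(ph, dir)
  expect_true(all(file.exists(file.path(dir, c("volume.nii.gz",
                                               "truth.nii.gz", "seeds.json",
                                               "run.json")))))
  expect_identical(load_labels(file.path(dir, "truth.nii.gz")), ph$truth)
  vol <- load_volume(file.path(dir, "volume.nii.gz"))
  expect_equal(vol$voxels, ph$volume$voxels, tolerance = 1e-3,
               ignore_attr = TRUE)                 # float32 storage on disk
  sj <- read_seeds(file.path(dir, "seeds.json"))
  expect_identical(sj$slice, ph$initial_slice)
  expect_identical(nrow(sj$seeds), nrow(ph$seeds))
})
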
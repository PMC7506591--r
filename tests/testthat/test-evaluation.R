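test_that("Dice follows 2TP/(FP + 2TP + FN) and handles empty masks", {
  a <- matrix(0L, 10, 10); a[2:7, 2:7] <- 1L
  expect_equal(dice(a, a), 1)
  b <- matrix(0L, 10, 10); b[9:10, 9:10] <- 1L
  expect_equal(dice(a, b), 0)
  cc <- structure(list(tp = 50, fp = 10, fn = 10, tn = 30),
                  class = "confusion_counts")
  expect_equal(dice(cc), 100 / 120)
  # both masks empty: undefined, never 0
  expect_true(is.na(dice(matrix(0L, 3, 3), matrix(0L, 3, 3))))
  # symmetric in prediction and reference
  set.seed(8)
  x <- matrix(rbinom(100, 1, 0.4), 10); y <- matrix(rbinom(100, 1, 0.4), 10)
  expect_equal(dice(x, y), dice(y, x))
})

test_that("FPR/FNR are normalised by the reference-positive count", {
  ref <- matrix(0L, 20, 20); ref[5:14, 5:14] <- 1L          # 100 positives
  pred <- ref; pred[15:19, 5:14] <- 1L                      # +50 FP
  r <- fpr_fnr(pred, ref)
  expect_equal(unname(r), c(0.5, 0))
  expect_equal(unname(fpr_fnr(ref, ref)), c(0, 0))
  expect_equal(fpr_fnr(matrix(0L, 20, 20), ref)[["fnr"]], 1)
  expect_true(all(is.na(fpr_fnr(pred, matrix(0L, 20, 20)))))
})

test_that("Hausdorff distance matches hand values and the double-loop oracle", {
  A <- matrix(c(0, 0), 1, 2)
  expect_equal(hausdorff(A, A), 0)
  expect_equal(hausdorff(A, matrix(c(3, 4), 1, 2)), 5)      # 3-4-5 triangle
  # two squares offset by 2 pixels
  sq <- as.matrix(expand.grid(1:5, 1:5))
  expect_equal(hausdorff(sq, sq + 2), hausdorff_oracle(sq, sq + 2))
  set.seed(31)
  for (k in 1:6) {
    A <- cbind(sample(60, sample(5:40, 1), TRUE), sample(60, 1, TRUE))
    B <- cbind(sample(60, sample(5:40, 1), TRUE), sample(60, 1, TRUE))
    A <- matrix(sample(100, 2 * sample(5:50, 1), TRUE), ncol = 2)
    B <- matrix(sample(100, 2 * sample(5:50, 1), TRUE), ncol = 2)
    expect_equal(hausdorff(A, B), hausdorff_oracle(A, B), tolerance = 1e-10)
  }
  # mm scaling
  expect_equal(hausdorff(A, B, scale = c(2, 2)), 2 * hausdorff(A, B))
  expect_true(is.na(hausdorff(A[0, , drop = FALSE], B)))
})

test_that("Dice obeys the symmetric-difference identity on random masks", {
  set.seed(13)
  for (k in 1:10) {
    a <- matrix(rbinom(400, 1, 0.3), 20)
    b <- matrix(rbinom(400, 1, 0.3), 20)
    if (sum(a) + sum(b) == 0) next
    d1 <- dice(a, b)
    d2 <- 1 - sum(xor(a, b)) / (sum(a) + sum(b))
    expect_equal(d1, d2)
  }
})

test_that("stack comparison reports per-category metrics like the clinic tables", {
  ph <- shared_phantom()
  rep0 <- compare_stacks(ph$truth, ph$truth, spacing = ph$volume$spacing)
  expect_true(all(rep0$dice == 1))
  expect_true(all(rep0$fpr == 0) && all(rep0$fnr == 0))
  expect_true(all(rep0$hd_px == 0))
  expect_identical(rep0$category, setdiff(rw_categories(), "background"))

  # a category absent from the reference is NA ("no manual delineations")
  ref <- ph$truth
  ref[ref == rwcontour:::category_code("gtv")] <-
    rwcontour:::category_code("lungs")
  rep1 <- compare_stacks(ph$truth, ref)
  expect_true(is.na(rep1$dice[rep1$category == "gtv"]))
  expect_identical(rep1$n_slices[rep1$category == "gtv"], 0L)
  expect_error(compare_stacks(ph$truth[1:3, , ], ph$truth), "shapes")

  # CSV round trip preserves the numbers
  path <- tempfile(fileext = ".csv")
  write_metrics(rep0, path)
  back <- read.csv(path)
  expect_equal(back$dice, rep0$dice)
  expect_equal(back$hd_mm, rep0$hd_mm)
})

test_that("slice-wise stack Hausdorff agrees with the point-set definition", {
  pred <- array(rw_background_code(), c(1, 30, 30))
  ref <- pred
  pred[1, 5:14, 5:14] <- 2L
  ref[1, 7:16, 6:15] <- 2L
  rep <- compare_stacks(pred, ref, categories = "lungs")
  hd <- hausdorff(boundary_points(pred[1, , ] == 2L),
                  boundary_points(ref[1, , ] == 2L))
  expect_equal(rep$hd_px, hd)
})
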
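test_that("Gaussian edge weights are symmetric, bounded and monotone", {
  expect_equal(edge_weight(100, 100, 70), 1)
  expect_equal(edge_weight(0, 25.5, 70), exp(-0.7))  # normalised gap 0.1
  g <- matrix(sample(0:255, 40, replace = TRUE), ncol = 2)
  expect_equal(edge_weight(g[, 1], g[, 2], 70), edge_weight(g[, 2], g[, 1], 70))
  d <- seq(0, 255, by = 5)
  w <- edge_weight(0, d, 70)
  expect_true(all(diff(w) <= 0))                     # larger gap, never larger w
  expect_true(all(w > 0 & w <= 1))
})

test_that("lattice graphs have the right edges and a proper Laplacian", {
  g2 <- build_graph(matrix(100L, 2, 2), rw_roi(1, 2, 1, 2), beta = 70)
  expect_identical(nrow(g2$edges), 4L)
  expect_true(all(abs(g2$edges$w - 1 - 1e-6) < 1e-12))  # uniform + eps floor
  expect_true(all(abs(Matrix::rowSums(g2$laplacian)) < 1e-12))

  g3 <- build_graph(matrix(sample(0:255, 9), 3, 3), rw_roi(1, 3, 1, 3))
  expect_identical(nrow(g3$edges), 12L)              # 2*3*(3-1) lattice edges
  L <- g3$laplacian
  expect_true(Matrix::isSymmetric(L))
  ev <- eigen(as.matrix(L), symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > -1e-10)                      # positive semidefinite
  expect_true(min(abs(ev)) < 1e-10)                  # 1-vector in null space
  expect_error(build_graph(matrix(0L, 4, 4), rw_roi(1, 8, 1, 4)), "bounds")
})

test_that("the Dirichlet solve is exact on a symmetric chain", {
  g <- pixel_graph(1, 3, i = c(1, 2), j = c(2, 3), w = c(1, 1))
  s <- data.frame(row = c(1, 1), col = c(1, 3), label = c("body", "lungs"))
  p <- solve_dirichlet(g, s)
  expect_equal(p[1, 2, "body"], 0.5, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(p[1, 2, "lungs"], 0.5, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(p[1, 1, "body"], 1, ignore_attr = TRUE)  # seed keeps its label
})

test_that("sparse solve matches an independent dense solve on random lattices", {
  set.seed(11)
  for (k in 1:12) {
    nr <- sample(2:8, 1); nc <- sample(2:8, 1)
    g <- mk_lattice(nr, nc)
    s <- mk_seeds(nr, nc, sample(2:4, 1))
    p <- solve_dirichlet(g, s)
    ref <- dense_dirichlet(g, s)
    expect_lt(max(abs(p - ref)), 1e-8)
    # conservation and the maximum principle
    expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-6)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("solver output matches Monte-Carlo absorption on a small lattice", {
  set.seed(3)
  g <- mk_lattice(5, 5)
  s <- mk_seeds(5, 5, 3)
  p <- solve_dirichlet(g, s)
  pm <- rw_mc_absorb(g, s, n_walks = 2e4, rng_seed = 99)
  sig <- sqrt(pmax(p * (1 - p), 1e-12) / 2e4)
  z <- abs(p - pm) / sig
  expect_true(mean(z <= 3) >= 0.99)
  expect_true(all(z <= 5))
})

test_that("permuting label identities permutes the probability maps", {
  set.seed(5)
  g <- mk_lattice(6, 6)
  pos <- data.frame(row = c(1, 6, 3), col = c(1, 6, 4))
  a <- cbind(pos, label = c("body", "lungs", "heart"))
  b <- cbind(pos, label = c("heart", "body", "lungs"))
  pa <- solve_dirichlet(g, a)
  pb <- solve_dirichlet(g, b)
  for (i in seq_len(nrow(pos))) {
    expect_equal(pa[, , a$label[i]], pb[, , b$label[i]], tolerance = 1e-8)
  }
})

test_that("argmax labelling respects seeds and the priority tie order", {
  probs <- array(0, c(1, 3, 3), dimnames = list(NULL, NULL,
                                                c("body", "lungs", "gtv")))
  probs[1, 1, ] <- c(0.7, 0.2, 0.1)
  probs[1, 2, ] <- c(0.5, 0.5, 0.0)   # exact tie: body wins (priority)
  probs[1, 3, ] <- c(0.1, 0.2, 0.7)
  lm <- assign_labels(probs)
  expect_identical(as.vector(lm),
                   c(rwcontour:::category_code(c("body", "body", "gtv"))))
  # a seed overrides any probability pattern
  seeds <- data.frame(row = 1L, col = 3L, label = "gtv")
  probs[1, 3, ] <- c(1, 0, 0)
  lm2 <- assign_labels(probs, seeds)
  expect_identical(lm2[1, 3], rwcontour:::category_code("gtv"))
})

test_that("an unseeded disconnected component is reported, not silently solved", {
  g <- pixel_graph(1, 4, i = c(1, 3), j = c(2, 4), w = c(1, 1))
  s <- data.frame(row = c(1, 1), col = c(1, 2), label = c("body", "lungs"))
  expect_error(solve_dirichlet(g, s), "disconnected")
  expect_error(solve_dirichlet(g, s[1, ]), "two distinct labels")
  dup <- data.frame(row = c(1, 1), col = c(1, 1), label = c("body", "lungs"))
  expect_error(solve_dirichlet(g, dup), "two different")
})
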
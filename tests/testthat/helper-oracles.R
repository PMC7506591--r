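# Independent oracles and fixture builders used across the test files.
# Every oracle is a deliberately naive implementation (dense solve, offset
# loops, double loops) kept separate from the code paths it checks.

## 4-connected lattice with supplied or random positive weights
mk_lattice <- function(nr, nc, weights = NULL) {
  idx <- matrix(seq_len(nr * nc), nr, nc)
  i <- c(idx[-nr, , drop = FALSE], idx[, -nc, drop = FALSE])
  j <- c(idx[-1, , drop = FALSE], idx[, -1, drop = FALSE])
  if (is.null(weights)) weights <- runif(length(i), 0.1, 1)
  pixel_graph(nr, nc, i, j, weights)
}

## random seeds on distinct pixels of an nr x nc lattice (at least one pixel
## stays unseeded)
mk_seeds <- function(nr, nc, n_labels) {
  n_labels <- min(n_labels, nr * nc - 1L)
  pos <- sample(nr * nc, n_labels)
  data.frame(row = (pos - 1L) %% nr + 1L, col = (pos - 1L) %/% nr + 1L,
             label = rw_categories()[seq_len(n_labels)])
}

## dense direct Dirichlet solve with base::solve (no sparse code, no
## complement trick: every label is solved independently)
dense_dirichlet <- function(graph, seeds) {
  L <- as.matrix(graph$laplacian)
  labels <- rw_categories()[sort(match(unique(seeds$label), rw_categories()))]
  node <- (seeds$col - 1L) * graph$nr + seeds$row
  un <- setdiff(seq_len(graph$n), node)
  probs <- array(0, dim = c(graph$nr, graph$nc, length(labels)),
                 dimnames = list(NULL, NULL, labels))
  for (k in seq_along(labels)) {
    b <- as.numeric(seeds$label == labels[k])
    x <- solve(L[un, un, drop = FALSE], -L[un, node, drop = FALSE] %*% b)
    pk <- numeric(graph$n)
    pk[node] <- b
    pk[un] <- x
    probs[, , k] <- matrix(pk, graph$nr, graph$nc)
  }
  probs
}

## brute-force binary erosion: a pixel survives iff every disk offset stays
## inside the mask (outside the image counts as background)
erode_oracle <- function(mask, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  offs <- which(disc_kernel(r) == 1L, arr.ind = TRUE) - r - 1L
  for (rr in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!mask[rr, cc]) next
    keep <- TRUE
    for (k in seq_len(nrow(offs))) {
      r2 <- rr + offs[k, 1L]; c2 <- cc + offs[k, 2L]
      if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc || !mask[r2, c2]) {
        keep <- FALSE; break
      }
    }
    if (keep) out[rr, cc] <- 1L
  }
  out
}

## O(|A||B|) double-loop Hausdorff
hausdorff_oracle <- function(A, B) {
  h <- function(X, Y) {
    worst <- 0
    for (i in seq_len(nrow(X))) {
      best <- Inf
      for (j in seq_len(nrow(Y))) {
        best <- min(best, sqrt(sum((X[i, ] - Y[j, ])^2)))
      }
      worst <- max(worst, best)
    }
    worst
  }
  max(h(A, B), h(B, A))
}

## random connected blob: dilations of a random walk trail
mk_blob <- function(nr = 48, nc = 48, steps = 60, grow = 2) {
  m <- matrix(0L, nr, nc)
  p <- c(sample(8:(nr - 8), 1), sample(8:(nc - 8), 1))
  for (i in seq_len(steps)) {
    m[p[1], p[2]] <- 1L
    p <- pmin(pmax(p + sample(c(-1L, 0L, 1L), 2, replace = TRUE), 4L),
              c(nr - 3L, nc - 3L))
  }
  blob <- EBImage::dilate(m, disc_kernel(grow))
  matrix(as.integer(as.array(blob) != 0), nr, nc)
}

## circle rasterised independently of the Hough code: angle sweep + rounding
circle_points <- function(center, radius, n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  unique(cbind(row = round(center[1] + radius * sin(th)),
               col = round(center[2] + radius * cos(th))))
}

## small shared phantom, generated once per test run
shared_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- phantom_generate(phantom_spec(shape = c(40, 160, 160)))
    cache
  }
})
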
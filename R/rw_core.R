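## Random-walker core: Gaussian edge weights on the 4-connected pixel lattice,
## combinatorial Laplacian, and the seeded Dirichlet solve that yields
## per-label first-arrival probabilities.

#' Gaussian edge weight between two grey levels
#'
#' `w = exp(-beta * ((g_i - g_j)/255)^2)`. Grey levels (0..255) are rescaled
#' to \[0, 1\] before the Gaussian: with raw 8-bit differences a typical
#' `beta = 70` would annihilate all contrast (`exp(-70)` underflows), so the
#' weighting is only meaningful on normalised intensities.
#'
#' @param g_i,g_j grey levels in 0..255 (vectorised).
#' @param beta positive contrast parameter; default 70.
#' @return weights in (0, 1\], symmetric in `g_i`, `g_j`.
#' @export
#' @examples
#' edge_weight(100, 100, 70)      # 1: zero gradient
#' edge_weight(0, 25.5, 70)       # exp(-0.7)
edge_weight <- function(g_i, g_j, beta = 70) {
  stopifnot(beta > 0)
  exp(-beta * ((g_i - g_j) / 255)^2)
}

#' Construct a pixel graph from explicit edges
#'
#' Low-level constructor used by [build_graph()] and by tests that need
#' arbitrary lattices. Edges are undirected; the Laplacian is assembled as
#' degree minus weighted adjacency.
#'
#' @param nr,nc lattice dimensions (rows, cols).
#' @param i,j integer endpoint node indices (column-major within the lattice,
#'   `index = (col-1)*nr + row`), one entry per undirected edge.
#' @param w strictly positive edge weights.
#' @param roi optional [rw_roi()] locating the lattice inside a full image.
#' @return object of class `pixel_graph`.
#' @export
pixel_graph <- function(nr, nc, i, j, w, roi = NULL) {
  n <- as.integer(nr) * as.integer(nc)
  stopifnot(length(i) == length(j), length(w) == length(i), all(w > 0),
            all(i >= 1), all(j >= 1), all(i <= n), all(j <= n), all(i != j))
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(n, n))
  L <- Matrix::Diagonal(x = Matrix::colSums(A)) - A
  structure(list(nr = as.integer(nr), nc = as.integer(nc), n = n,
                 edges = data.frame(i = as.integer(i), j = as.integer(j),
                                    w = as.numeric(w)),
                 laplacian = L, roi = roi),
            class = "pixel_graph")
}

#' Build the 4-connected weighted lattice over an ROI
#'
#' Edge weights come from [edge_weight()] on the windowed grey levels; a small
#' additive `eps` keeps the graph connected through flat zero-contrast regions.
#'
#' @param slice_gray integer matrix of windowed grey levels (full image).
#' @param roi a [rw_roi()]; must lie inside the image.
#' @param beta contrast parameter, default 70.
#' @param eps additive weight floor, default 1e-6.
#' @return a [pixel_graph()] whose nodes are the ROI pixels.
#' @export
build_graph <- function(slice_gray, roi, beta = 70, eps = 1e-6) {
  check_roi(roi, dim(slice_gray))
  g <- slice_gray[roi$row_min:roi$row_max, roi$col_min:roi$col_max,
                  drop = FALSE]
  nr <- nrow(g); nc <- ncol(g)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  # vertical edges (row, row+1) and horizontal edges (col, col+1)
  i <- c(idx[-nr, , drop = FALSE], idx[, -nc, drop = FALSE])
  j <- c(idx[-1, , drop = FALSE], idx[, -1, drop = FALSE])
  w <- edge_weight(g[i], g[j], beta) + eps
  pixel_graph(nr, nc, i, j, w, roi = roi)
}

## absolute (row, col) -> local lattice node index
graph_node_index <- function(graph, row, col) {
  if (!is.null(graph$roi)) {
    row <- row - graph$roi$row_min + 1L
    col <- col - graph$roi$col_min + 1L
  }
  if (any(row < 1L | row > graph$nr | col < 1L | col > graph$nc)) {
    stop("seed coordinates outside the graph ROI")
  }
  (col - 1L) * graph$nr + row
}

validate_seeds <- function(seeds) {
  stopifnot(is.data.frame(seeds), all(c("row", "col", "label") %in% names(seeds)))
  category_code(seeds$label)            # errors on unknown labels
  key <- paste(seeds$row, seeds$col)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    lab <- vapply(dup, function(k) length(unique(seeds$label[key == k])),
                  integer(1))
    if (any(lab > 1L)) stop("a pixel carries two different seed labels")
    seeds <- seeds[!duplicated(key), , drop = FALSE]
  }
  seeds
}

#' Solve the combinatorial Dirichlet problem for seeded labels
#'
#' For each label, computes the harmonic function on the pixel graph with
#' boundary value 1 on that label's seeds and 0 on all other seeds — the
#' probability that a random walk started at each pixel, stepping with
#' probabilities proportional to edge weights, first reaches a seed of that
#' label. The sparse symmetric system is solved by direct Cholesky
#' factorisation; only K-1 labels are solved, the last is obtained by
#' complement.
#'
#' @param graph a [pixel_graph()].
#' @param seeds data.frame with columns `row`, `col`, `label` (absolute image
#'   coordinates when the graph has an ROI, lattice coordinates otherwise);
#'   at least two distinct labels.
#' @return 3D array `[nr, nc, K]` of class `probability_maps`;
#'   `dimnames[[3]]` are the labels in priority order. Per-pixel sums are 1
#'   and seed pixels carry probability exactly 1 for their own label.
#' @export
solve_dirichlet <- function(graph, seeds) {
  stopifnot(inherits(graph, "pixel_graph"))
  seeds <- validate_seeds(seeds)
  labels <- rw_categories()[sort(unique(category_code(seeds$label)))]
  if (length(labels) < 2L) stop("need seeds of at least two distinct labels")
  node <- graph_node_index(graph, seeds$row, seeds$col)
  n <- graph$n
  K <- length(labels)

  seeded <- logical(n); seeded[node] <- TRUE
  un <- which(!seeded)
  probs <- array(0, dim = c(graph$nr, graph$nc, K),
                 dimnames = list(NULL, NULL, labels))
  # boundary values at seeds
  for (k in seq_len(K)) {
    pk <- matrix(0, graph$nr, graph$nc)
    pk[node[seeds$label == labels[k]]] <- 1
    probs[, , k] <- pk
  }
  if (length(un)) {
    L <- graph$laplacian
    Luu <- L[un, un, drop = FALSE]
    Lus <- L[un, node, drop = FALSE]
    B <- matrix(0, length(node), K - 1L)
    for (k in seq_len(K - 1L)) B[seeds$label == labels[k], k] <- 1
    rhs <- as.matrix(-Lus %*% B)
    x <- tryCatch(
      suppressWarnings(
        as.matrix(Matrix::solve(Matrix::Cholesky(Luu, LDL = FALSE), rhs))),
      error = function(e) {
        comp <- unseeded_components(graph, seeded)
        if (!is.null(comp)) {
          stop(sprintf(
            "graph has an unseeded component disconnected from all seeds (%d pixels, e.g. node %d)",
            comp$size, comp$example), call. = FALSE)
        }
        stop("Dirichlet system is singular: ", conditionMessage(e),
             call. = FALSE)
      })
    for (k in seq_len(K - 1L)) {
      pk <- probs[, , k]
      pk[un] <- x[, k]
      probs[, , k] <- pmin(pmax(pk, 0), 1)
    }
    last <- matrix(1, graph$nr, graph$nc) -
      apply(probs[, , seq_len(K - 1L), drop = FALSE], c(1, 2), sum)
    lastv <- probs[, , K]
    last[node] <- lastv[node]           # keep exact boundary values at seeds
    probs[, , K] <- pmin(pmax(last, 0), 1)
  }
  structure(probs, class = c("probability_maps", "array"))
}

## BFS from seeds; returns NULL if everything is reachable, else a description
## of one unreached component
unseeded_components <- function(graph, seeded) {
  n <- graph$n
  adj <- vector("list", n)
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    adj[[e$i[r]]] <- c(adj[[e$i[r]]], e$j[r])
    adj[[e$j[r]]] <- c(adj[[e$j[r]]], e$i[r])
  }
  seen <- seeded
  queue <- which(seeded)
  while (length(queue)) {
    nb <- unique(unlist(adj[queue]))
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    queue <- nb
  }
  if (all(seen)) return(NULL)
  bad <- which(!seen)
  list(size = length(bad), example = bad[1L])
}

#' Assign each pixel the most probable label
#'
#' Argmax over the probability maps; seeded pixels always keep their seeded
#' label; exact ties break by the fixed priority order of [rw_categories()]
#' (body < lungs < airway < heart < spinal_cord < gtv < background).
#'
#' @param probs a `probability_maps` array from [solve_dirichlet()].
#' @param seeds the seed data.frame used for the solve (same coordinate
#'   convention), or NULL.
#' @param roi optional [rw_roi()] used to translate absolute seed coordinates.
#' @return integer matrix `[nr, nc]` of category codes.
#' @export
assign_labels <- function(probs, seeds = NULL, roi = NULL) {
  labels <- dimnames(probs)[[3L]]
  codes <- category_code(labels)
  prio <- order(codes)                  # priority order = category order
  m <- matrix(probs, ncol = length(labels))[, prio, drop = FALSE]
  best <- max.col(m, ties.method = "first")
  lab <- matrix(codes[prio][best], dim(probs)[1L], dim(probs)[2L])
  if (!is.null(seeds) && nrow(seeds)) {
    row <- seeds$row; col <- seeds$col
    if (!is.null(roi)) {
      row <- row - roi$row_min + 1L
      col <- col - roi$col_min + 1L
    }
    lab[cbind(row, col)] <- category_code(seeds$label)
  }
  lab
}

#' Monte-Carlo absorption probabilities (simulation cross-check)
#'
#' Independent stochastic estimate of the quantities computed analytically by
#' [solve_dirichlet()]: simulates discrete random walks stepping with
#' probability proportional to edge weight until a seed is hit, and returns
#' per-label absorption frequencies. Used to validate the solver; far too slow
#' for segmentation itself.
#'
#' @inheritParams solve_dirichlet
#' @param n_walks walks per unseeded pixel.
#' @param rng_seed integer seed for the internal RNG.
#' @return array like [solve_dirichlet()]'s result.
#' @export
rw_mc_absorb <- function(graph, seeds, n_walks = 1e5, rng_seed = 1L) {
  stopifnot(inherits(graph, "pixel_graph"))
  seeds <- validate_seeds(seeds)
  labels <- rw_categories()[sort(unique(category_code(seeds$label)))]
  node <- graph_node_index(graph, seeds$row, seeds$col)
  n <- graph$n
  e <- graph$edges
  deg <- tabulate(c(e$i, e$j), n)
  ord <- order(c(e$i, e$j))
  nbr <- c(e$j, e$i)[ord]
  wt <- c(e$w, e$w)[ord]
  ptr <- c(0L, cumsum(deg))             # CSR row pointers, 0-based
  lab_of_seed <- integer(n)             # 0 = unseeded
  lab_of_seed[node] <- match(seeds$label, labels)
  counts <- mc_absorb_cpp(ptr, nbr - 1L, wt, lab_of_seed, length(labels),
                          as.integer(n_walks), as.integer(rng_seed))
  probs <- array(0, dim = c(graph$nr, graph$nc, length(labels)),
                 dimnames = list(NULL, NULL, labels))
  for (k in seq_along(labels)) {
    pk <- counts[, k] / n_walks
    pk[node] <- as.numeric(lab_of_seed[node] == k)
    probs[, , k] <- matrix(pk, graph$nr, graph$nc)
  }
  structure(probs, class = c("probability_maps", "array"))
}

#' Read / write seed files
#'
#' Seed files are JSON:
#' `{"slice": <int>, "coordinate_convention": "0-based (row, col)",
#'   "seeds": [{"label": "lungs", "row": 10, "col": 12}, ...]}`.
#' File coordinates are 0-based; in-memory data.frames are 1-based.
#'
#' @param path JSON file path.
#' @return `read_seeds`: list with `slice` (1-based) and `seeds` data.frame.
#' @export
read_seeds <- function(path) {
  x <- jsonlite::fromJSON(path)
  seeds <- data.frame(row = as.integer(x$seeds$row) + 1L,
                      col = as.integer(x$seeds$col) + 1L,
                      label = as.character(x$seeds$label))
  list(slice = as.integer(x$slice) + 1L, seeds = validate_seeds(seeds))
}

#' @rdname read_seeds
#' @param slice 1-based slice index the seeds live on.
#' @param seeds data.frame with `row`, `col`, `label` (1-based).
#' @export
write_seeds <- function(slice, seeds, path) {
  seeds <- validate_seeds(seeds)
  jsonlite::write_json(
    list(slice = slice - 1L,
         coordinate_convention = "0-based (row, col)",
         seeds = data.frame(label = seeds$label,
                            row = seeds$row - 1L, col = seeds$col - 1L)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
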
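## Automatic seed generation for slice-by-slice propagation: boundary erosion
## of the previous segmentation, skeleton sampling as the rescue path for thin
## regions, and the Hounsfield-unit knowledge filter that removes bad seeds.

#' Erosion policy for seed generation
#'
#' Regions larger than `area_threshold` pixels are eroded with a disk of
#' radius `large_radius`, smaller regions with `small_radius`, before seed
#' points are sampled from the eroded boundary.
#'
#' @param area_threshold pixel-count threshold between large and small
#'   targets (default 1000).
#' @param large_radius,small_radius disk radii in pixels (defaults 12 and 1).
#' @return object of class `erosion_policy`.
#' @export
erosion_policy <- function(area_threshold = 1000, large_radius = 12,
                           small_radius = 1) {
  stopifnot(area_threshold > 0, large_radius >= 1, small_radius >= 1)
  structure(list(area_threshold = area_threshold,
                 large_radius = as.integer(large_radius),
                 small_radius = as.integer(small_radius)),
            class = "erosion_policy")
}

#' Disk structuring element
#'
#' Binary disk `x^2 + y^2 <= r^2` on a (2r+1) square grid.
#'
#' @param r integer radius in pixels.
#' @return 0/1 integer matrix.
#' @export
disc_kernel <- function(r) {
  r <- as.integer(r)
  d <- seq(-r, r)
  k <- outer(d^2, d^2, "+") <= r^2
  storage.mode(k) <- "integer"
  k
}

as_mask <- function(x) {
  m <- matrix(as.integer(as.array(x) != 0), nrow(x), ncol(x))
  m
}

## binary erosion with the image border treated as background (EBImage keeps
## out-of-image pixels at foreground, so pad with zeros first)
erode_mask <- function(mask, r) {
  mask <- as_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(0L, nr + 2L * r, nc + 2L * r)
  p[(r + 1L):(r + nr), (r + 1L):(r + nc)] <- mask
  e <- as_mask(EBImage::erode(p, disc_kernel(r)))
  e[(r + 1L):(r + nr), (r + 1L):(r + nc), drop = FALSE]
}

#' Erode one region mask according to the policy
#'
#' @param mask binary matrix (one category's region on one slice).
#' @param policy an [erosion_policy()].
#' @return eroded binary matrix (possibly empty — the caller falls back to
#'   skeleton seeds in that case).
#' @export
erode_region <- function(mask, policy = erosion_policy()) {
  mask <- as_mask(mask)
  area <- sum(mask)
  if (area == 0L) return(mask)
  r <- if (area > policy$area_threshold) policy$large_radius else policy$small_radius
  erode_mask(mask, r)
}

## inner boundary: pixels of the mask with a 4-neighbour outside it
region_boundary <- function(mask) {
  mask <- as_mask(mask)
  if (!sum(mask)) return(mask)
  mask & !erode_mask(mask, 1L)
}

## systematic (every n/k-th point, random start) sample: every point has equal
## inclusion probability and the picks spread evenly along the candidate list,
## which is in image scan order
sample_pixels <- function(coords, count_ratio, rng_seed, max_count) {
  n <- nrow(coords)
  k <- max(1L, as.integer(round(count_ratio * n)))
  k <- min(k, n, max_count)
  if (k >= n) return(coords)
  stride <- n / k
  start <- with_rng(rng_seed, runif(1, 0, stride))
  pick <- pmin(n, floor(start + stride * (seq_len(k) - 1L)) + 1L)
  coords[unique(pick), , drop = FALSE]
}

#' Sample seed points on the boundary of an eroded region
#'
#' @param eroded binary matrix from [erode_region()]; must be non-empty.
#' @param label category label to attach to the seeds.
#' @param count_ratio fraction of boundary pixels to sample (default 0.05);
#'   the count is `max(1, round(ratio * boundary length))`, capped at
#'   `max_count`.
#' @param rng_seed integer seed; the sample is deterministic under it.
#' @param max_count cap on the number of seeds (default 20).
#' @return data.frame with columns `row`, `col`, `label` (empty if the mask
#'   is empty — the signal for the skeleton fallback).
#' @export
sample_boundary_seeds <- function(eroded, label, count_ratio = 0.05,
                                  rng_seed = 1L, max_count = 20L) {
  b <- region_boundary(eroded)
  if (!sum(b)) {
    return(data.frame(row = integer(), col = integer(), label = character()))
  }
  coords <- which(b != 0L, arr.ind = TRUE)
  pick <- sample_pixels(coords, count_ratio, rng_seed, max_count)
  data.frame(row = as.integer(pick[, 1L]), col = as.integer(pick[, 2L]),
             label = label)
}

#' Morphological skeleton by Zhang-Suen thinning
#'
#' Iteratively peels boundary pixels (two sub-iterations per pass) until the
#' region is one pixel wide. The skeleton is always a subset of the mask.
#'
#' @param mask binary matrix.
#' @return binary matrix of the skeleton.
#' @export
skeletonize <- function(mask) {
  m <- as_mask(mask)
  if (!sum(m)) return(m)
  zhang_suen_cpp(m)
}

## 8-neighbour count of skeleton pixels
skeleton_degree <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- skel
  acc <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    acc <- acc + p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc),
                   drop = FALSE]
  }
  acc
}

#' Prune short spur branches from a skeleton
#'
#' Walks inward from each endpoint; branches shorter than `min_branch`
#' pixels that terminate at a junction are removed (one pass). Short
#' isolated skeletons without junctions are kept.
#'
#' @param skel binary skeleton matrix.
#' @param min_branch minimum branch length kept, default 5.
#' @return pruned binary matrix.
#' @export
prune_skeleton <- function(skel, min_branch = 5L) {
  skel <- as_mask(skel)
  if (sum(skel) <= 1L) return(skel)
  deg <- skeleton_degree(skel)
  ends <- which(skel == 1L & deg == 1L, arr.ind = TRUE)
  if (!nrow(ends)) return(skel)
  out <- skel
  nbrs <- expand.grid(dr = -1:1, dc = -1:1)
  nbrs <- nbrs[!(nbrs$dr == 0 & nbrs$dc == 0), ]
  for (e in seq_len(nrow(ends))) {
    path <- matrix(ends[e, ], ncol = 2)
    cur <- ends[e, ]
    hit_junction <- FALSE
    while (nrow(path) < min_branch) {
      cand <- cbind(cur[1] + nbrs$dr, cur[2] + nbrs$dc)
      ok <- cand[, 1] >= 1 & cand[, 1] <= nrow(skel) &
            cand[, 2] >= 1 & cand[, 2] <= ncol(skel)
      cand <- cand[ok, , drop = FALSE]
      on <- cand[skel[cand] == 1L, , drop = FALSE]
      on <- on[!(paste(on[, 1], on[, 2]) %in% paste(path[, 1], path[, 2])), ,
               drop = FALSE]
      if (nrow(on) == 0L) break                    # isolated short line: keep
      if (nrow(on) > 1L || deg[on[1, 1], on[1, 2]] >= 3L) {
        hit_junction <- TRUE
        break
      }
      cur <- on[1, ]
      path <- rbind(path, cur)
    }
    if (hit_junction) out[path] <- 0L
  }
  if (!sum(out)) skel else out
}

#' Sample seeds from the (pruned) skeleton of a region
#'
#' Rescue path for regions that erosion would annihilate: the region is
#' thinned to a one-pixel skeleton, spur branches are pruned, and
#' `max(1, round(ratio * skeleton size))` points are sampled uniformly.
#'
#' @inheritParams sample_boundary_seeds
#' @param mask binary region mask (uneroded).
#' @param prune_len spur-branch pruning length, default 5.
#' @return data.frame `row`, `col`, `label`; empty with attribute
#'   `vanished = TRUE` when the mask itself is empty.
#' @export
skeleton_seeds <- function(mask, label, count_ratio = 0.05, rng_seed = 1L,
                           max_count = 20L, prune_len = 5L) {
  mask <- as_mask(mask)
  if (!sum(mask)) {
    out <- data.frame(row = integer(), col = integer(), label = character())
    attr(out, "vanished") <- TRUE
    return(out)
  }
  # thin on a cropped bounding box for speed
  rr <- range(which(rowSums(mask) > 0)); cc <- range(which(colSums(mask) > 0))
  sub <- mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  sk <- prune_skeleton(skeletonize(sub), prune_len)
  coords <- which(sk == 1L, arr.ind = TRUE)
  if (!nrow(coords)) {
    # thinning can annihilate very small blobs; keep the most central pixel
    coords <- which(sub == 1L, arr.ind = TRUE)
    ctr <- colMeans(coords)
    coords <- coords[which.min((coords[, 1L] - ctr[1L])^2 +
                                 (coords[, 2L] - ctr[2L])^2), , drop = FALSE]
  }
  coords[, 1L] <- coords[, 1L] + rr[1] - 1L
  coords[, 2L] <- coords[, 2L] + cc[1] - 1L
  pick <- sample_pixels(coords, count_ratio, rng_seed, max_count)
  data.frame(row = as.integer(pick[, 1L]), col = as.integer(pick[, 2L]),
             label = label)
}

#' Grey-level knowledge table
#'
#' Per-category admissible windowed grey levels, derived from the anatomical
#' HU table through the soft-tissue window: air-filled categories (lungs,
#' airway, background) have grey 0..10; soft-tissue categories (body, gtv,
#' heart) have grey >= 10; the spinal cord excludes grey 255 (bone).
#'
#' @return named list of predicate functions of the grey level.
#' @export
hu_knowledge_table <- function() {
  list(
    body        = function(g) g >= 10,
    lungs       = function(g) g <= 10,
    airway      = function(g) g <= 10,
    heart       = function(g) g >= 10,
    spinal_cord = function(g) g != 255,
    gtv         = function(g) g >= 10,
    background  = function(g) g <= 10
  )
}

#' Remove seeds whose grey level contradicts their label
#'
#' Each seed is checked against the knowledge-table predicate for its label,
#' evaluated at the seed's position on the *next* slice (the slice the seeds
#' are intended for). Order is preserved; the filter is idempotent.
#'
#' @param seeds data.frame `row`, `col`, `label`.
#' @param next_slice_gray integer matrix of windowed grey levels of the
#'   target slice.
#' @param table knowledge table from [hu_knowledge_table()].
#' @return filtered data.frame; attribute `starved` lists labels that lost
#'   all their seeds.
#' @export
filter_bad_seeds <- function(seeds, next_slice_gray,
                             table = hu_knowledge_table()) {
  if (!nrow(seeds)) {
    attr(seeds, "starved") <- character()
    return(seeds)
  }
  g <- next_slice_gray[cbind(seeds$row, seeds$col)]
  keep <- vapply(seq_len(nrow(seeds)),
                 function(i) isTRUE(table[[seeds$label[i]]](g[i])),
                 logical(1))
  out <- seeds[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "starved") <- setdiff(unique(seeds$label), unique(out$label))
  out
}

#' Generate next-slice seeds from the current segmentation
#'
#' Per category and per connected component, seed candidates come from two
#' sources: the boundary of the eroded region ([erode_region()]) and the
#' pruned skeleton of the uneroded region ([skeleton_seeds()]); the skeleton
#' keeps thin or annular regions seeded when erosion annihilates or
#' fragments them. A sample of the candidate union is then screened by
#' [filter_bad_seeds()] against the next slice. If screening starves a
#' component whose candidate points would still pass somewhere, admissible
#' candidates are re-admitted (up to the per-category cap), so a category
#' only loses all seeds when it has truly vanished.
#'
#' @param labelmap integer matrix of category codes (current slice result).
#' @param next_slice_gray windowed grey levels of the slice to be seeded.
#' @param policy an [erosion_policy()].
#' @param table knowledge table.
#' @param count_ratio,max_count,prune_len see [sample_boundary_seeds()] /
#'   [skeleton_seeds()].
#' @param rng_seed pipeline-level seed; split deterministically per
#'   (slice, category, component).
#' @param slice_index index used in the per-category RNG split.
#' @param skip_labels labels never propagated (default `background`, which
#'   the pipeline re-seeds from the ROI border on every slice).
#' @return data.frame `row`, `col`, `label` with attributes `vanished`
#'   (categories absent from `labelmap`) and `starved` (categories whose
#'   seeds were all removed by the grey-level filter).
#' @export
propagate_seeds <- function(labelmap, next_slice_gray,
                            policy = erosion_policy(),
                            table = hu_knowledge_table(),
                            count_ratio = 0.05, max_count = 20L,
                            prune_len = 5L, rng_seed = 1L, slice_index = 0L,
                            skip_labels = "background") {
  cats <- setdiff(rw_categories(), skip_labels)
  present <- intersect(cats, category_name(sort(unique(as.integer(labelmap)))))
  out <- list(); starved <- character()
  for (lab in present) {
    code <- category_code(lab)
    mask <- as_mask(labelmap == code)
    comps <- as_mask_labels(mask)
    cand_all <- NULL; sampled <- NULL
    for (ci in seq_len(max(comps))) {
      comp <- as_mask(comps == ci)
      sd_i <- derive_seed(rng_seed, slice_index, code, ci)
      er <- erode_region(comp, policy)
      sk <- skeleton_seeds(comp, lab, count_ratio = 1, rng_seed = sd_i,
                           max_count = .Machine$integer.max,
                           prune_len = prune_len)
      cand <- rbind(which(region_boundary(er) != 0L, arr.ind = TRUE),
                    cbind(sk$row, sk$col))
      cand <- cand[!duplicated(paste(cand[, 1L], cand[, 2L])), , drop = FALSE]
      if (!nrow(cand)) next
      pick <- sample_pixels(cand, count_ratio, sd_i, max_count)
      keep_df <- data.frame(row = pick[, 1L], col = pick[, 2L], label = lab)
      kept <- filter_bad_seeds(keep_df, next_slice_gray, table)
      if (!nrow(kept)) {
        # rescue: re-admit admissible candidates so the component only dies
        # when no candidate matches its grey-level predicate
        all_df <- data.frame(row = cand[, 1L], col = cand[, 2L], label = lab)
        ok <- filter_bad_seeds(all_df, next_slice_gray, table)
        if (nrow(ok)) {
          kept <- sample_pixels(cbind(ok$row, ok$col), count_ratio, sd_i,
                                max_count)
          kept <- data.frame(row = kept[, 1L], col = kept[, 2L], label = lab)
        }
      }
      if (nrow(kept)) sampled <- rbind(sampled, kept)
    }
    if (is.null(sampled) || !nrow(sampled)) starved <- c(starved, lab)
    else out[[lab]] <- sampled
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(row = integer(), col = integer(), label = character())
  rownames(res) <- NULL
  res <- res[!duplicated(paste(res$row, res$col)), , drop = FALSE]
  attr(res, "vanished") <- setdiff(cats, present)
  attr(res, "starved") <- starved
  res
}

## connected-component labelling (EBImage bwlabel) returning an int matrix
as_mask_labels <- function(mask) {
  lb <- EBImage::bwlabel(as_mask(mask))
  m <- matrix(as.integer(as.array(lb)), nrow(mask), ncol(mask))
  m
}
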
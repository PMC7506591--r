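## Agreement metrics between a predicted and a reference label stack:
## Dice = 2TP / (FP + 2TP + FN), false-positive / false-negative rates
## normalised by the reference-positive count, and the symmetric Hausdorff
## distance between boundary point sets.

#' Confusion counts between two binary masks
#'
#' @param pred,ref binary arrays of identical shape (prediction, reference).
#' @return list of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, ref) {
  stopifnot(all(dim(pred) == dim(ref)))
  p <- as.logical(pred); r <- as.logical(ref)
  structure(list(tp = sum(p & r), fp = sum(p & !r),
                 fn = sum(!p & r), tn = sum(!p & !r)),
            class = "confusion_counts")
}

#' Dice coefficient
#'
#' `2TP / (FP + 2TP + FN)`; 1 iff the masks agree exactly. When both masks
#' are empty the coefficient is undefined and `NA` is returned (never 0).
#'
#' @param counts a [confusion_counts()] object, or a prediction mask when
#'   `ref` is given.
#' @param ref optional reference mask.
#' @return Dice coefficient in \[0, 1\], or `NA` if undefined.
#' @export
dice <- function(counts, ref = NULL) {
  if (!is.null(ref)) counts <- confusion_counts(counts, ref)
  stopifnot(inherits(counts, "confusion_counts"))
  denom <- counts$fp + 2 * counts$tp + counts$fn
  if (denom == 0) return(NA_real_)
  2 * counts$tp / denom
}

#' False-positive and false-negative rates
#'
#' Both are normalised by the reference-positive count `TP + FN`:
#' `FPR = FP / (TP + FN)`, `FNR = FN / (TP + FN)`. (With this normalisation
#' the FPR can exceed 1 for gross over-segmentation.) Undefined (`NA`) when
#' the reference mask is empty.
#'
#' @inheritParams dice
#' @return named numeric vector `c(fpr = , fnr = )`.
#' @export
fpr_fnr <- function(counts, ref = NULL) {
  if (!is.null(ref)) counts <- confusion_counts(counts, ref)
  stopifnot(inherits(counts, "confusion_counts"))
  refpos <- counts$tp + counts$fn
  if (refpos == 0) return(c(fpr = NA_real_, fnr = NA_real_))
  c(fpr = counts$fp / refpos, fnr = counts$fn / refpos)
}

#' Boundary points of a binary mask
#'
#' Inner boundary: mask pixels with a 4-neighbour outside the mask.
#'
#' @param mask binary matrix.
#' @return matrix with columns `row`, `col`.
#' @export
boundary_points <- function(mask) {
  pts <- which(region_boundary(mask) != 0L, arr.ind = TRUE)
  colnames(pts) <- c("row", "col")
  pts
}

## directed max-min distance from A to B (chunked to bound memory)
directed_hausdorff <- function(A, B, scale) {
  As <- sweep(A, 2L, scale, "*"); Bs <- sweep(B, 2L, scale, "*")
  h <- 0
  step <- max(1L, floor(2e6 / nrow(Bs)))
  for (s in seq(1L, nrow(As), by = step)) {
    blk <- As[s:min(s + step - 1L, nrow(As)), , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(Bs^2), "+") -
      2 * tcrossprod(blk, Bs)
    h <- max(h, sqrt(pmax(apply(d2, 1L, min), 0)))
  }
  h
}

#' Symmetric Hausdorff distance between two point sets
#'
#' `max( max_a min_b d(a,b), max_b min_a d(a,b) )` with Euclidean distance;
#' coordinates may be scaled per axis (e.g. pixel spacing in mm).
#'
#' @param A,B non-empty point matrices (one point per row, same number of
#'   columns).
#' @param scale per-axis multiplier applied before measuring distance
#'   (default all 1: distances in pixels).
#' @return the Hausdorff distance, or `NA` if either set is empty.
#' @export
hausdorff <- function(A, B, scale = rep(1, ncol(A))) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!nrow(A) || !nrow(B)) return(NA_real_)
  stopifnot(ncol(A) == ncol(B), length(scale) == ncol(A))
  max(directed_hausdorff(A, B, scale), directed_hausdorff(B, A, scale))
}

#' Compare two label stacks category by category
#'
#' Computes per-category confusion counts (over the slices where the
#' reference delineates the category), Dice, FPR/FNR, and the Hausdorff
#' distance. The Hausdorff distance is evaluated slice-wise in 2D on the
#' in-plane boundary point sets and the maximum over slices is reported, in
#' pixels and in mm (in-plane spacing). A category never present in the
#' reference is reported as `NA` (no reference delineation, not zero
#' agreement).
#'
#' @param pred,ref integer 3D label arrays `[slice, row, col]` of category
#'   codes, identical shapes.
#' @param spacing voxel spacing (slice, row, col) in mm.
#' @param categories category names to evaluate (default all but
#'   `background`).
#' @return data.frame with one row per category: `category`, `dice`, `fpr`,
#'   `fnr`, `hd_px`, `hd_mm`, `n_slices`; attribute `summary` holds the
#'   mean and sd of the defined Dice values.
#' @export
compare_stacks <- function(pred, ref, spacing = c(2.5, 1, 1),
                           categories = setdiff(rw_categories(), "background")) {
  pred <- as.array(pred); ref <- as.array(ref)
  if (!all(dim(pred) == dim(ref))) stop("label stacks have different shapes")
  rows <- lapply(categories, function(cat) {
    code <- category_code(cat)
    ref_sl <- which(apply(ref == code, 1L, any))
    if (!length(ref_sl)) {
      return(data.frame(category = cat, dice = NA_real_, fpr = NA_real_,
                        fnr = NA_real_, hd_px = NA_real_, hd_mm = NA_real_,
                        n_slices = 0L))
    }
    cc <- confusion_counts(pred[ref_sl, , , drop = FALSE] == code,
                           ref[ref_sl, , , drop = FALSE] == code)
    rates <- fpr_fnr(cc)
    hd <- NA_real_; hd_mm <- NA_real_
    for (s in ref_sl) {
      bp <- boundary_points(pred[s, , ] == code)
      br <- boundary_points(ref[s, , ] == code)
      if (nrow(bp) && nrow(br)) {
        h <- hausdorff(bp, br)
        hmm <- hausdorff(bp, br, scale = spacing[2:3])
        hd <- if (is.na(hd)) h else max(hd, h)
        hd_mm <- if (is.na(hd_mm)) hmm else max(hd_mm, hmm)
      }
    }
    data.frame(category = cat, dice = dice(cc), fpr = rates[["fpr"]],
               fnr = rates[["fnr"]], hd_px = hd,
               hd_mm = hd_mm, n_slices = length(ref_sl))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  d <- out$dice[!is.na(out$dice)]
  attr(out, "summary") <- c(mean_dice = mean(d), sd_dice = sd(d))
  out
}

#' Write a metric report to CSV
#'
#' @param report data.frame from [compare_stacks()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
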
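## CT volume I/O and grey-level windowing.
##
## Internal array convention: voxels[slice, row, col], slices ordered
## inferior -> superior. All user-facing file coordinates (seed and contour
## JSON) are 0-based; in-memory R objects are 1-based.

#' Construct a CT volume
#'
#' @param voxels 3D numeric array of Hounsfield units, indexed
#'   `[slice, row, col]`, slices ordered inferior to superior.
#' @param spacing numeric length-3: slice thickness, row pixel size, column
#'   pixel size, all in mm.
#' @return An object of class `ct_volume` with elements `voxels`, `spacing`,
#'   `slice_count`.
#' @export
ct_volume <- function(voxels, spacing = c(2.5, 1, 1)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (!all(is.finite(voxels))) stop("HU values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be 3 strictly positive values (mm)")
  }
  structure(list(voxels = voxels, spacing = spacing,
                 slice_count = dim(voxels)[1L]),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("CT volume: %d slices x %d x %d px, spacing %.2f x %.2f x %.2f mm, HU [%d, %d]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              round(min(x$voxels)), round(max(x$voxels))))
  invisible(x)
}

#' Rectangular region of interest
#'
#' @param row_min,row_max,col_min,col_max 1-based inclusive pixel bounds.
#' @return Object of class `rw_roi`.
#' @export
rw_roi <- function(row_min, row_max, col_min, col_max) {
  stopifnot(row_min < row_max, col_min < col_max, row_min >= 1, col_min >= 1)
  structure(list(row_min = as.integer(row_min), row_max = as.integer(row_max),
                 col_min = as.integer(col_min), col_max = as.integer(col_max)),
            class = "rw_roi")
}

roi_dims <- function(roi) {
  c(roi$row_max - roi$row_min + 1L, roi$col_max - roi$col_min + 1L)
}

check_roi <- function(roi, img_dim) {
  if (roi$row_max > img_dim[1L] || roi$col_max > img_dim[2L]) {
    stop("ROI exceeds image bounds")
  }
  invisible(roi)
}

#' Soft-tissue grey-level window
#'
#' Linearly maps the soft-tissue Hounsfield window \[-140, 260\] HU onto grey
#' levels 0..255; values below/above the window clamp to 0/255. Rounding is
#' half-away-from-zero. This windowed image is the sole input of the
#' random-walker edge weights and of the HU knowledge filter.
#'
#' @param slice_hu numeric matrix (or array) of finite HU values.
#' @return Integer array of the same shape with values in 0..255.
#' @export
#' @examples
#' window_soft_tissue(c(-1000, -140, 60, 260, 1000))
window_soft_tissue <- function(slice_hu) {
  if (!all(is.finite(slice_hu))) stop("HU values must be finite")
  g <- 255 * (slice_hu + 140) / 400
  g <- pmin(pmax(g, 0), 255)
  out <- as.integer(floor(g + 0.5))      # half-away-from-zero; g >= 0 here
  ans <- slice_hu
  ans[] <- out
  storage.mode(ans) <- "integer"
  ans
}

#' Convert stored CT integers to Hounsfield units
#'
#' Applies the linear rescale `HU = slope * stored + intercept` used by CT
#' scanners to map stored pixel values to Hounsfield units.
#'
#' @param stored numeric stored values.
#' @param slope,intercept rescale slope and intercept; both must be supplied
#'   (volumes without them are rejected rather than guessed).
#' @return numeric HU values.
#' @export
hu_from_stored <- function(stored, slope, intercept) {
  if (missing(slope) || missing(intercept) ||
      is.null(slope) || is.null(intercept) ||
      !is.finite(slope) || !is.finite(intercept)) {
    stop("rescale slope/intercept missing; refusing to guess HU calibration")
  }
  slope * stored + intercept
}

#' Read a CT volume from NIfTI
#'
#' Reads a `.nii`/`.nii.gz` volume, reorders axes to the internal
#' `[slice, row, col]` convention and returns Hounsfield units (NIfTI scale
#' slope/intercept applied by the reader). The third NIfTI axis is taken as
#' the slice axis, ordered inferior to superior.
#'
#' @param path path to a NIfTI file.
#' @return A [ct_volume()].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3L) stop("expected a 3D volume, got ",
                                 length(dim(a)), " dimensions")
  pd <- RNifti::pixdim(img)     # (x, y, z) = (col, row, slice)
  vox <- aperm(a, c(3L, 2L, 1L))
  ct_volume(vox, spacing = c(pd[3L], pd[2L], pd[1L]))
}

#' Write a CT volume to NIfTI
#'
#' Inverse of [load_volume()]: round-trips voxel values and spacing.
#'
#' @param volume a [ct_volume()].
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  a <- aperm(volume$voxels, c(3L, 2L, 1L))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- volume$spacing[c(3L, 2L, 1L)]
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write a label-map stack with category sidecar
#'
#' Writes one multi-label NIfTI volume (integer category codes) plus a plain
#' text sidecar mapping codes to category names, and optionally one binary
#' NIfTI mask per category.
#'
#' @param labels integer 3D array `[slice, row, col]` of category codes
#'   (positions in [rw_categories()]).
#' @param path output path for the label volume (`.nii`/`.nii.gz`).
#' @param spacing voxel spacing (slice, row, col) in mm.
#' @param per_category also write one binary mask per category present.
#' @return `path`, invisibly.
#' @export
write_masks <- function(labels, path, spacing = c(2.5, 1, 1),
                        per_category = FALSE) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  a <- aperm(labels, c(3L, 2L, 1L))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- spacing[c(3L, 2L, 1L)]
  RNifti::writeNifti(img, path, datatype = "int16")
  side <- sub("\\.nii(\\.gz)?$", "", path)
  cats <- rw_categories()
  writeLines(c("code\tcategory",
               sprintf("%d\t%s", seq_along(cats), cats)),
             paste0(side, "_labels.txt"))
  if (per_category) {
    for (k in sort(unique(as.integer(labels)))) {
      if (k < 1L || k > length(cats)) next
      m <- aperm(array(as.integer(labels == k), dim(labels)), c(3L, 2L, 1L))
      mi <- RNifti::asNifti(m)
      RNifti::pixdim(mi) <- spacing[c(3L, 2L, 1L)]
      RNifti::writeNifti(mi, paste0(side, "_", cats[k], ".nii.gz"),
                         datatype = "uint8")
    }
  }
  invisible(path)
}

#' Read a label-map stack written by [write_masks()]
#'
#' @param path NIfTI label volume path.
#' @return integer 3D array `[slice, row, col]`.
#' @export
load_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  a <- as.array(RNifti::readNifti(path))
  storage.mode(a) <- "integer"
  aperm(a, c(3L, 2L, 1L))
}
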
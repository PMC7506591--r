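## Synthetic thoracic CT phantom: primitive-based organs (elliptical-cylinder
## body, ellipsoidal lungs and heart, bifurcating airway, spinal cord inside a
## vertebral ring, a tumour abutting the chest wall, and a deliberately thin
## muscle sheet) with Hounsfield means anchored to the anatomical HU table and
## additive Gaussian noise. Ground-truth masks are exact by construction.

#' Phantom specification
#'
#' Geometry is expressed at a reference grid of 80 slices x 256 x 256 pixels
#' (2.5 / 1 / 1 mm spacing) and rescaled proportionally for other shapes.
#' Tissue HU means follow the anatomical table: air -1000, lung -500 (within
#' the -600..-400 lung range), fat-dominated body -50, muscle/soft tissue
#' 30..40 (tumour, cord, heart, muscle sheet), bone 700. Noise is additive
#' Gaussian, default sd 20 HU.
#'
#' @param shape volume shape `c(slices, rows, cols)`, default `c(80, 256, 256)`.
#' @param spacing voxel spacing (slice, row, col) in mm.
#' @param noise_sd Gaussian HU noise standard deviation, default 20.
#' @param rng_seed integer seed controlling noise and seed sampling.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(80, 256, 256), spacing = c(2.5, 1, 1),
                         noise_sd = 20, rng_seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 16))
  S <- shape[1L]; R <- shape[2L]; C <- shape[3L]
  fs <- S / 80; fr <- R / 256; fc <- C / 256
  geom <- list(
    body    = list(center = c(132 * fr, 128 * fc), semi = c(78 * fr, 102 * fc),
                   taper = 0.15, rim = 0.92),
    lungs   = list(row = 118 * fr, cols = c(80, 176) * fc,
                   semi = c(50 * fr, 36 * fc), z_center = 40 * fs,
                   z_semi = 32 * fs),
    heart   = list(appear = max(2L, round(15 * fs)),
                   disappear = round(48 * fs),
                   center = c(142 * fr, 118 * fc), semi = c(26 * fr, 36 * fc)),
    airway  = list(trachea_center = c(96 * fr, 128 * fc), trachea_r = 6 * fc,
                   trachea_top = round(76 * fs), junction = round(45 * fs),
                   bronchus_r = 5 * fc, bronchus_bottom = max(2L, round(12 * fs)),
                   offset0 = 6 * fc, offset_rate = 0.35 * fc / fs,
                   offset_max = 8 * fc, row_rate = 0.2 * fr / fs,
                   row_max = 6 * fr),
    spine   = list(center = c(186 * fr, 128 * fc), cord_r = 7 * fc,
                   bone_outer = 16 * fc),
    tumor   = list(center = c(118 * fr, 60 * fc), r = 13 * fc,
                   z_center = 40 * fs, z_semi = 8 * fs),
    muscle  = list(rho = 0.80, col_min = 188 * fc,
                   slices = round(c(20, 60) * fs))
  )
  hu <- c(air = -1000, fat = -60, muscle = 30, lung = -500, airway = -1000,
          heart = 40, cord = 35, bone = 700, tumor = 30)
  structure(list(shape = as.integer(shape), spacing = spacing,
                 noise_sd = noise_sd, rng_seed = as.integer(rng_seed),
                 geom = geom, hu = hu),
            class = "phantom_spec")
}

## pick k interior points of a mask, eroding first when possible
interior_points <- function(mask, erode_r, k, rng_seed) {
  er <- if (erode_r > 0) erode_mask(mask, erode_r) else as_mask(mask)
  if (!sum(er)) er <- as_mask(mask)
  coords <- which(er == 1L, arr.ind = TRUE)
  pick <- coords[with_rng(rng_seed, sample.int(nrow(coords),
                                               min(k, nrow(coords)))), ,
                 drop = FALSE]
  data.frame(row = as.integer(pick[, 1L]), col = as.integer(pick[, 2L]))
}

## one interior point per grid cell, spreading seeds across a large region
## the way a user clicks body seeds all around the slice
grid_points <- function(mask, erode_r, cell, rng_seed, max_k = 16L) {
  er <- if (erode_r > 0) erode_mask(mask, erode_r) else as_mask(mask)
  if (!sum(er)) er <- as_mask(mask)
  coords <- which(er == 1L, arr.ind = TRUE)
  key <- paste((coords[, 1L] - 1L) %/% cell, (coords[, 2L] - 1L) %/% cell)
  idx <- with_rng(rng_seed, vapply(split(seq_len(nrow(coords)), key),
                                   function(ii) ii[sample.int(length(ii), 1L)],
                                   integer(1)))
  if (length(idx) > max_k) {
    idx <- idx[with_rng(rng_seed + 1L, sort(sample.int(length(idx), max_k)))]
  }
  pick <- coords[idx, , drop = FALSE]
  data.frame(row = as.integer(pick[, 1L]), col = as.integer(pick[, 2L]))
}

#' Generate a synthetic thoracic CT phantom
#'
#' Returns the noisy HU volume, the exact ground-truth label stack, a ready
#' [run_config()] (true heart range and airway junction) and a valid initial
#' seed set on the mid-thorax slice, with all seeds strictly inside their
#' organs. Deterministic under the spec's `rng_seed`.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `rw_phantom` with elements `volume` ([ct_volume()]),
#'   `truth` (integer array of category codes), `config`, `seeds`
#'   (data.frame), `initial_slice`.
#' @export
phantom_generate <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  S <- spec$shape[1L]; R <- spec$shape[2L]; C <- spec$shape[3L]
  g <- spec$geom; hu <- spec$hu
  rows <- seq_len(R); cols <- seq_len(C)
  truth <- array(rw_background_code(), dim = c(S, R, C))
  huv <- array(hu[["air"]], dim = c(S, R, C))
  code <- category_code

  for (s in seq_len(S)) {
    lab <- matrix(rw_background_code(), R, C)
    hm <- matrix(hu[["air"]], R, C)

    # body: fat interior with a muscle/skin rim at the surface
    sc <- 1 - g$body$taper * ((s - S / 2) / (S / 2))^2
    brho <- sqrt(outer(((rows - g$body$center[1]) / (g$body$semi[1] * sc))^2,
                       ((cols - g$body$center[2]) / (g$body$semi[2] * sc))^2,
                       "+"))
    body <- brho <= 1
    lab[body] <- code("body")
    hm[body & brho < g$body$rim] <- hu[["fat"]]
    hm[body & brho >= g$body$rim] <- hu[["muscle"]]

    tz <- 1 - ((s - g$lungs$z_center) / g$lungs$z_semi)^2
    lung_masks <- list()
    if (tz > 0) {
      for (li in 1:2) {
        lm <- outer(((rows - g$lungs$row) / (g$lungs$semi[1] * sqrt(tz)))^2,
                    ((cols - g$lungs$cols[li]) / (g$lungs$semi[2] * sqrt(tz)))^2,
                    "+") <= 1
        lung_masks[[li]] <- lm
        lab[lm] <- code("lungs"); hm[lm] <- hu[["lung"]]
      }
      # thin muscle sheet along the chest wall inside the right lung: the
      # two-pixel inner rim of a slightly shrunken lung ellipse, minus any
      # staircase pixel that would survive a radius-1 erosion (so the sheet
      # reliably exercises the seeds-vanishing rescue path)
      if (s >= g$muscle$slices[1] && s <= g$muscle$slices[2]) {
        E <- outer(((rows - g$lungs$row) / (g$lungs$semi[1] * sqrt(tz)))^2,
                   ((cols - g$lungs$cols[2]) / (g$lungs$semi[2] * sqrt(tz)))^2,
                   "+") <= g$muscle$rho[1]^2
        E <- matrix(as.integer(E), R, C)
        arc <- (E & !erode_mask(E, 2L)) &
          matrix(cols >= g$muscle$col_min, R, C, byrow = TRUE) &
          lung_masks[[2]]
        arc <- arc & !erode_mask(matrix(as.integer(arc), R, C), 1L)
        lab[arc] <- code("body"); hm[arc] <- hu[["muscle"]]
        lung_masks[[2]] <- lung_masks[[2]] & !arc
      }
    }

    # heart cross-section (assigned below, but needed to carve the pleural
    # shell: the heart is embedded in pericardial fat, not muscle)
    hmask <- NULL
    if (s >= g$heart$appear && s <= g$heart$disappear) {
      zc <- (g$heart$appear + g$heart$disappear) / 2
      zs <- (g$heart$disappear - g$heart$appear) / 2 + 1
      htz <- 1 - ((s - zc) / zs)^2
      if (htz > 0) {
        hmask <- outer(((rows - g$heart$center[1]) / (g$heart$semi[1] * sqrt(htz)))^2,
                       ((cols - g$heart$center[2]) / (g$heart$semi[2] * sqrt(htz)))^2,
                       "+") <= 1
      }
    }

    # pleural / chest-wall soft tissue: a thin muscle shell hugging the lungs
    # (the strong lung/soft-tissue CT edge), leaving fat elsewhere
    if (tz > 0) {
      both <- lung_masks[[1]] | lung_masks[[2]]
      shell <- as_mask(EBImage::dilate(as_mask(both), disc_kernel(3L))) == 1L &
        !both & lab == code("body")
      if (!is.null(hmask)) {
        near_heart <- as_mask(EBImage::dilate(as_mask(hmask),
                                              disc_kernel(4L))) == 1L
        shell <- shell & !near_heart
      }
      hm[shell] <- hu[["muscle"]]
    }

    if (!is.null(hmask)) {
      lab[hmask] <- code("heart"); hm[hmask] <- hu[["heart"]]
    }

    # tumour: sphere-like ellipsoid inside the left lung, abutting lung
    # parenchyma on all sides
    ttz <- 1 - ((s - g$tumor$z_center) / g$tumor$z_semi)^2
    if (ttz > 0 && length(lung_masks)) {
      tr <- g$tumor$r * sqrt(ttz)
      tmask <- outer((rows - g$tumor$center[1])^2,
                     (cols - g$tumor$center[2])^2, "+") <= tr^2
      tmask <- tmask & lung_masks[[1]]
      lab[tmask] <- code("gtv"); hm[tmask] <- hu[["tumor"]]
    }

    # airway: single trachea above the junction, two bronchi below
    aw <- g$airway
    if (s >= aw$junction && s <= aw$trachea_top) {
      am <- outer((rows - aw$trachea_center[1])^2,
                  (cols - aw$trachea_center[2])^2, "+") <= aw$trachea_r^2
      lab[am] <- code("airway"); hm[am] <- hu[["air"]]
    } else if (s >= aw$bronchus_bottom && s < aw$junction) {
      dz <- aw$junction - s
      off <- min(aw$offset0 + aw$offset_rate * dz, aw$offset_max)
      drow <- min(aw$row_rate * dz, aw$row_max)
      for (sgn in c(-1, 1)) {
        am <- outer((rows - (aw$trachea_center[1] + drow))^2,
                    (cols - (aw$trachea_center[2] + sgn * off))^2,
                    "+") <= aw$bronchus_r^2
        lab[am] <- code("airway"); hm[am] <- hu[["air"]]
      }
    }

    # airway wall: soft-tissue ring around the lumen (tracheal/bronchial wall)
    awm <- lab == code("airway")
    if (any(awm)) {
      wall <- as_mask(EBImage::dilate(as_mask(awm), disc_kernel(2L))) == 1L &
        !awm & lab == code("body")
      hm[wall] <- hu[["muscle"]]
    }

    # vertebra ring (bone, body category) with the spinal cord inside
    d2 <- outer((rows - g$spine$center[1])^2, (cols - g$spine$center[2])^2, "+")
    bone <- d2 > g$spine$cord_r^2 & d2 <= g$spine$bone_outer^2
    lab[bone] <- code("body"); hm[bone] <- hu[["bone"]]
    cordm <- d2 <= g$spine$cord_r^2
    lab[cordm] <- code("spinal_cord"); hm[cordm] <- hu[["cord"]]

    truth[s, , ] <- lab
    huv[s, , ] <- hm
  }

  phantom_validate(truth, spec)

  noise <- with_rng(derive_seed(spec$rng_seed, 1L, 1L, 1L),
                    rnorm(length(huv), 0, spec$noise_sd))
  vol <- ct_volume(huv + noise, spacing = spec$spacing)

  s0 <- as.integer(round(S / 2))
  seeds <- phantom_initial_seeds(truth[s0, , ], spec)
  config <- run_config(initial_slice = s0,
                       heart_range = c(g$heart$appear, g$heart$disappear),
                       junction_slice = g$airway$junction,
                       rng_seed = spec$rng_seed)
  structure(list(volume = vol, truth = truth, config = config, seeds = seeds,
                 initial_slice = s0, spec = spec),
            class = "rw_phantom")
}

phantom_validate <- function(truth, spec) {
  g <- spec$geom
  code <- category_code
  inside_body <- truth != rw_background_code()
  for (cat in c("lungs", "airway", "heart", "spinal_cord", "gtv")) {
    if (!all(inside_body[truth == code(cat)])) {
      stop("phantom geometry violation: ", cat, " outside the body")
    }
  }
  hr <- c(g$heart$appear, g$heart$disappear)
  hs <- which(apply(truth == code("heart"), 1L, any))
  if (length(hs) && (min(hs) < hr[1] || max(hs) > hr[2])) {
    stop("phantom geometry violation: heart outside its slice range")
  }
  for (s in seq_len(dim(truth)[1L])) {
    am <- truth[s, , ] == code("airway")
    if (!any(am)) next
    ncomp <- max(as_mask_labels(am))
    want <- if (s >= g$airway$junction) 1L else 2L
    if (ncomp != want) {
      stop(sprintf("phantom geometry violation: %d airway components on slice %d (expected %d)",
                   ncomp, s, want))
    }
  }
  invisible(TRUE)
}

## initial seeds on one slice, sampled strictly inside the true organs
phantom_initial_seeds <- function(truth_slice, spec) {
  code <- category_code
  base <- spec$rng_seed
  out <- list()
  plan <- list(lungs = c(erode = 3, k = 3), airway = c(erode = 1, k = 1),
               heart = c(erode = 3, k = 3), gtv = c(erode = 2, k = 2),
               body = c(erode = 5, k = 4))
  for (cat in names(plan)) {
    mask <- truth_slice == code(cat)
    if (!any(mask)) next
    comps <- as_mask_labels(mask)
    for (ci in seq_len(max(comps))) {
      comp <- comps == ci
      sd_ci <- derive_seed(base, 0L, code(cat), ci)
      pts <- if (cat == "body" && sum(comp) >= 1000) {
        # spread body seeds on a coarse grid, as a user clicking all around
        grid_points(comp, plan[[cat]][["erode"]],
                    cell = max(8L, as.integer(nrow(comp) / 6)), sd_ci)
      } else if (cat == "body" && sum(comp) < 1000) {
        interior_points(comp, 0L, 1L, sd_ci)
      } else {
        interior_points(comp, plan[[cat]][["erode"]], plan[[cat]][["k"]],
                        sd_ci)
      }
      if (nrow(pts)) out[[paste(cat, ci)]] <- cbind(pts, label = cat)
    }
  }
  # the spinal cord needs only one seed: its centre
  ctr <- round(spec$geom$spine$center)
  out$spinal_cord <- data.frame(row = ctr[1], col = ctr[2],
                                label = "spinal_cord")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  validate_seeds(res)
}

#' Degrade a phantom: blur boundaries and raise noise
#'
#' Stress fixture for weak-edge behaviour: each slice of the HU volume is
#' Gaussian-blurred (softening every organ boundary) and extra Gaussian noise
#' is added. The ground truth is unchanged. `sigma = 0` with zero extra noise
#' is the identity.
#'
#' @param phantom an `rw_phantom` from [phantom_generate()].
#' @param weak_edge_sigma Gaussian blur sigma in pixels (default 1.5).
#' @param noise_sigma extra HU noise sd (default 10).
#' @return the phantom with a degraded `volume`.
#' @export
phantom_degrade <- function(phantom, weak_edge_sigma = 1.5, noise_sigma = 10) {
  stopifnot(inherits(phantom, "rw_phantom"))
  v <- phantom$volume$voxels
  if (weak_edge_sigma > 0) {
    for (s in seq_len(dim(v)[1L])) {
      v[s, , ] <- as.matrix(EBImage::gblur(v[s, , ], sigma = weak_edge_sigma))
    }
  }
  if (noise_sigma > 0) {
    v <- v + with_rng(derive_seed(phantom$spec$rng_seed, 2L, 2L, 2L),
                      rnorm(length(v), 0, noise_sigma))
  }
  phantom$volume <- ct_volume(v, spacing = phantom$volume$spacing)
  phantom
}

#' Write a phantom to disk
#'
#' Writes the HU volume and truth labels as NIfTI, the initial seeds as JSON
#' and the run configuration as JSON.
#'
#' @param phantom an `rw_phantom`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
phantom_write <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(phantom$volume, file.path(dir, "volume.nii.gz"))
  write_masks(phantom$truth, file.path(dir, "truth.nii.gz"),
              spacing = phantom$volume$spacing)
  write_seeds(phantom$initial_slice, phantom$seeds,
              file.path(dir, "seeds.json"))
  cfg <- unclass(phantom$config)
  cfg$policy <- unclass(cfg$policy)
  jsonlite::write_json(cfg, file.path(dir, "run.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
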
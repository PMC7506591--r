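## Slice-by-slice orchestration: from one manually seeded slice, the volume is
## segmented bidirectionally (superior and inferior), each slice seeding the
## next through the seed engine, with heart-range gating, airway-junction
## bookkeeping and Hough-circle spinal-cord refinement.

#' Run configuration
#'
#' @param initial_slice 1-based index of the manually seeded slice.
#' @param heart_range `c(appear, disappear)` slice indices; heart seeds are
#'   dropped outside this range.
#' @param junction_slice slice of the trachea/bronchus junction; below it the
#'   airway is tracked as (at most) two components.
#' @param roi a [rw_roi()], or `NULL` to derive one from the initial slice
#'   via [suggest_roi()].
#' @param beta random-walker contrast parameter (default 70).
#' @param rng_seed master seed; every stochastic step derives its stream from
#'   it, so reruns are bit-identical.
#' @param count_ratio,max_seeds,prune_len seed-engine sampling parameters.
#' @param policy an [erosion_policy()].
#' @param min_component post-argmax components smaller than this are absorbed
#'   into the surrounding majority label (speckle suppression, default 5 px).
#' @param background_gray ROI-border pixels at or below this grey level are
#'   auto-seeded as background (default 10).
#' @param spine spinal-cord refinement parameters: `r_min`, `r_max`,
#'   `roi_halfwidth`, `edge_percentile`, `max_drift`, `min_edge_points`.
#' @param categories organ categories expected in the initial seeds.
#' @return list of class `run_config`.
#' @export
run_config <- function(initial_slice, heart_range, junction_slice,
                       roi = NULL, beta = 70, rng_seed = 1L,
                       count_ratio = 0.05, max_seeds = 20L, prune_len = 5L,
                       policy = erosion_policy(), min_component = 5L,
                       background_gray = 10L,
                       spine = list(r_min = 4L, r_max = 12L,
                                    roi_halfwidth = 25L,
                                    edge_percentile = 0.9, max_drift = 10,
                                    min_edge_points = 10L),
                       categories = setdiff(rw_categories(), "background")) {
  stopifnot(length(heart_range) == 2L, heart_range[1] <= heart_range[2])
  structure(list(initial_slice = as.integer(initial_slice),
                 heart_range = as.integer(heart_range),
                 junction_slice = as.integer(junction_slice),
                 roi = roi, beta = beta, rng_seed = as.integer(rng_seed),
                 count_ratio = count_ratio, max_seeds = as.integer(max_seeds),
                 prune_len = as.integer(prune_len), policy = policy,
                 min_component = as.integer(min_component),
                 background_gray = as.integer(background_gray),
                 spine = spine, categories = categories),
            class = "run_config")
}

#' Suggest a rectangular ROI around the body
#'
#' Bounding box of soft-tissue grey levels (> 10) on a slice, dilated by
#' `pad` pixels and clipped to the image.
#'
#' @param slice_gray windowed grey-level matrix.
#' @param pad dilation in pixels (default 10).
#' @return a [rw_roi()].
#' @export
suggest_roi <- function(slice_gray, pad = 10L) {
  hit <- which(slice_gray > 10L, arr.ind = TRUE)
  if (!nrow(hit)) stop("no soft-tissue pixels found; cannot suggest an ROI")
  rw_roi(max(1L, min(hit[, 1L]) - pad),
         min(nrow(slice_gray), max(hit[, 1L]) + pad),
         max(1L, min(hit[, 2L]) - pad),
         min(ncol(slice_gray), max(hit[, 2L]) + pad))
}

## absorb one component into the majority label of its surrounding ring
absorb_component <- function(lm, comp_mask) {
  ring <- as_mask(EBImage::dilate(as_mask(comp_mask), disc_kernel(1L))) &
    !comp_mask
  vals <- lm[ring]
  if (!length(vals)) return(lm)
  tab <- sort(table(vals), decreasing = TRUE)
  lm[comp_mask] <- as.integer(names(tab)[1L])
  lm
}

#' Absorb sub-threshold label components into their surroundings
#'
#' Suppresses argmax speckle: connected components of any category smaller
#' than `min_size` pixels take the majority label of their 1-pixel
#' neighbourhood ring.
#'
#' @param labelmap integer matrix of category codes.
#' @param min_size minimum component size kept (default 5).
#' @return cleaned label map.
#' @export
cleanup_small_components <- function(labelmap, min_size = 5L) {
  if (min_size <= 1L) return(labelmap)
  for (code in sort(unique(as.integer(labelmap)))) {
    comps <- as_mask_labels(labelmap == code)
    n <- max(comps)
    if (!n) next
    sizes <- tabulate(comps[comps > 0L], n)
    for (ci in which(sizes < min_size)) {
      labelmap <- absorb_component(labelmap, comps == ci)
    }
  }
  labelmap
}

#' Enforce the airway component budget below the junction
#'
#' Inferior to the junction slice the airway should consist of the two main
#' bronchi; any further components are absorbed into their surroundings (the
#' two largest are kept). At or above the junction the map is returned
#' unchanged.
#'
#' @param labelmap integer matrix of category codes.
#' @param slice_index current slice.
#' @param junction_slice junction slice index.
#' @return label map; attribute `airway_dropped` counts removed components.
#' @export
handle_junction <- function(labelmap, slice_index, junction_slice) {
  if (slice_index >= junction_slice) return(labelmap)
  comps <- as_mask_labels(labelmap == category_code("airway"))
  n <- max(comps)
  if (n <= 2L) return(labelmap)
  sizes <- tabulate(comps[comps > 0L], n)
  drop <- order(sizes, decreasing = TRUE)[-(1:2)]
  for (ci in drop) labelmap <- absorb_component(labelmap, comps == ci)
  attr(labelmap, "airway_dropped") <- length(drop)
  labelmap
}

#' Trace closed boundary polygons for every category
#'
#' Outer boundary pixel chains per connected component per category, as
#' closed polygons (first vertex repeated last). Interior holes are not
#' traced; rasterising a polygon back with [polygon_mask()] reproduces the
#' hole-filled component.
#'
#' @param labelmap integer matrix of category codes.
#' @param categories categories to trace (default all but background).
#' @return named list: category -> list of closed polygon matrices
#'   (columns `row`, `col`, 1-based).
#' @export
trace_contours <- function(labelmap,
                           categories = setdiff(rw_categories(), "background")) {
  out <- list()
  for (cat in categories) {
    mask <- as_mask(labelmap == category_code(cat))
    if (!sum(mask)) next
    oc <- EBImage::ocontour(EBImage::bwlabel(mask))
    polys <- lapply(oc, function(m) {
      p <- cbind(row = m[, 1L] + 1L, col = m[, 2L] + 1L)
      rbind(p, p[1L, , drop = FALSE])
    })
    out[[cat]] <- polys
  }
  out
}

#' Rasterise a closed boundary polygon back to a mask
#'
#' @param poly closed polygon matrix (columns row, col) from
#'   [trace_contours()].
#' @param dims `c(rows, cols)` of the target mask.
#' @return binary matrix.
#' @export
polygon_mask <- function(poly, dims) {
  m <- matrix(0L, dims[1L], dims[2L])
  m[poly] <- 1L
  as_mask(EBImage::fillHull(m))
}

#' Write a contour set as JSON
#'
#' One object per processed slice mapping category to a list of closed
#' polygons; coordinates are 0-based (row, col).
#'
#' @param contours contour list from [rw_run()] (`$contours`).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path) {
  slices <- list()
  for (s in seq_along(contours)) {
    if (is.null(contours[[s]])) next
    slices[[as.character(s - 1L)]] <-
      lapply(contours[[s]], function(polys) {
        lapply(polys, function(p) unname(p) - 1L)
      })
  }
  jsonlite::write_json(
    list(coordinate_convention = "0-based (row, col)", slices = slices),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Segment a CT volume from one seeded slice
#'
#' Segments the initial slice with the seeded random walker, then propagates
#' bidirectionally: each solved slice generates the next slice's seeds by
#' boundary erosion / skeleton sampling filtered through the grey-level
#' knowledge table. Heart seeds exist only inside `heart_range`; below the
#' junction slice the airway is held to two components; the spinal cord is
#' replaced by a Hough-fitted disk on every slice. Deterministic under
#' `config$rng_seed`.
#'
#' @param volume a [ct_volume()].
#' @param initial_seeds data.frame `row`, `col`, `label` (1-based, absolute)
#'   on the initial slice; every category in `config$categories` needs at
#'   least one seed (heart exempt when the initial slice lies outside
#'   `heart_range`).
#' @param config a [run_config()].
#' @param verbose print per-slice progress.
#' @return object of class `rw_result`: `labels` (integer array, full volume,
#'   background outside the ROI), `contours` (per slice, absolute
#'   coordinates), `circles` (per slice spinal-cord fit), `log` (per-slice
#'   data.frame: seeds used, starved categories, spine flag), `roi`,
#'   `config`.
#' @export
rw_run <- function(volume, initial_seeds, config, verbose = FALSE) {
  stopifnot(inherits(volume, "ct_volume"), inherits(config, "run_config"))
  dims <- dim(volume$voxels)
  S <- dims[1L]
  s0 <- config$initial_slice
  if (s0 < 1L || s0 > S) stop("initial_slice outside the volume")
  gray <- window_soft_tissue(volume$voxels)
  roi <- if (is.null(config$roi)) suggest_roi(gray[s0, , ]) else config$roi
  check_roi(roi, dims[2:3])
  G <- gray[, roi$row_min:roi$row_max, roi$col_min:roi$col_max, drop = FALSE]
  nr <- dim(G)[2L]; nc <- dim(G)[3L]

  seeds0 <- validate_seeds(initial_seeds)
  seeds0$row <- seeds0$row - roi$row_min + 1L
  seeds0$col <- seeds0$col - roi$col_min + 1L
  if (any(seeds0$row < 1L | seeds0$row > nr | seeds0$col < 1L |
            seeds0$col > nc)) {
    stop("initial seeds fall outside the ROI")
  }
  in_heart0 <- s0 >= config$heart_range[1L] && s0 <= config$heart_range[2L]
  required <- setdiff(config$categories,
                      c("background", if (!in_heart0) "heart"))
  missing <- setdiff(required, unique(seeds0$label))
  if (length(missing)) {
    stop("no initial seeds for categor", if (length(missing) > 1) "ies: " else "y: ",
         paste(missing, collapse = ", "))
  }

  local_stack <- array(rw_background_code(), dim = c(S, nr, nc))
  processed <- rep(FALSE, S)
  circles <- vector("list", S)
  contours <- vector("list", S)
  logs <- vector("list", S)

  seg_one <- function(s, seeds, circle) {
    gs <- matrix(G[s, , ], nr, nc)
    if (!(s >= config$heart_range[1L] && s <= config$heart_range[2L])) {
      seeds <- seeds[seeds$label != "heart", , drop = FALSE]
    }
    bg <- border_background_seeds(gs, config$background_gray)
    all_seeds <- rbind(seeds[, c("row", "col", "label")], bg)
    all_seeds <- all_seeds[!duplicated(paste(all_seeds$row, all_seeds$col)), ,
                           drop = FALSE]
    if (!nrow(all_seeds)) return(NULL)
    labs <- unique(all_seeds$label)
    if (length(labs) == 1L) {
      lm <- matrix(category_code(labs), nr, nc)
    } else {
      graph <- build_graph(gs, rw_roi(1L, nr, 1L, nc), beta = config$beta)
      probs <- solve_dirichlet(graph, all_seeds)
      lm <- assign_labels(probs, all_seeds)
      lm <- cleanup_small_components(lm, config$min_component)
      lm <- handle_junction(lm, s, config$junction_slice)
    }
    spine_flag <- FALSE
    if ("spinal_cord" %in% labs || !is.null(circle)) {
      sp <- config$spine
      rs <- refine_spine(lm, gs, circle, r_min = sp$r_min, r_max = sp$r_max,
                         halfwidth = sp$roi_halfwidth,
                         percentile = sp$edge_percentile,
                         max_drift = sp$max_drift,
                         min_points = sp$min_edge_points)
      lm <- rs$labelmap; circle <- rs$circle; spine_flag <- rs$flagged
    }
    list(lm = lm, circle = circle, spine_flag = spine_flag,
         seeds = all_seeds)
  }

  record <- function(s, res, starved) {
    local_stack[s, , ] <<- res$lm
    processed[s] <<- TRUE
    circles[[s]] <<- res$circle
    logs[[s]] <<- data.frame(
      slice = s, n_seeds = nrow(res$seeds),
      n_categories = length(unique(res$seeds$label)),
      starved = paste(starved, collapse = ","),
      spine_flagged = res$spine_flag)
  }

  res0 <- seg_one(s0, seeds0, NULL)
  if (is.null(res0)) stop("no usable seeds on the initial slice")
  record(s0, res0, character())
  if (verbose) message("slice ", s0, " (initial)")

  for (dir in c(1L, -1L)) {
    prev <- res0
    s <- s0 + dir
    while (s >= 1L && s <= S) {
      gs_next <- matrix(G[s, , ], nr, nc)
      seeds <- propagate_seeds(prev$lm, gs_next, policy = config$policy,
                               count_ratio = config$count_ratio,
                               max_count = config$max_seeds,
                               prune_len = config$prune_len,
                               rng_seed = config$rng_seed, slice_index = s)
      starved <- attr(seeds, "starved")
      if (!(s >= config$heart_range[1L] && s <= config$heart_range[2L])) {
        seeds <- seeds[seeds$label != "heart", , drop = FALSE]
      }
      if (!nrow(seeds) ||
          !any(seeds$label %in% setdiff(config$categories, "background"))) {
        warning("seed propagation starved at slice ", s,
                "; remaining slices in this direction left as background")
        logs[[s]] <- data.frame(slice = s, n_seeds = 0L, n_categories = 0L,
                                starved = paste(starved, collapse = ","),
                                spine_flagged = FALSE)
        break
      }
      res <- seg_one(s, seeds, prev$circle)
      record(s, res, starved)
      if (verbose) message("slice ", s, ": ", nrow(seeds), " seeds")
      prev <- res
      s <- s + dir
    }
  }

  labels_full <- array(rw_background_code(), dim = dims)
  for (s in which(processed)) {
    full <- matrix(rw_background_code(), dims[2L], dims[3L])
    full[roi$row_min:roi$row_max, roi$col_min:roi$col_max] <- local_stack[s, , ]
    labels_full[s, , ] <- full
    ctr <- trace_contours(full)
    contours[[s]] <- ctr
  }
  storage.mode(labels_full) <- "integer"

  structure(list(labels = labels_full, contours = contours,
                 circles = circles,
                 log = do.call(rbind, logs[!vapply(logs, is.null, TRUE)]),
                 roi = roi, config = config),
            class = "rw_result")
}

border_background_seeds <- function(gs, background_gray = 10L) {
  nr <- nrow(gs); nc <- ncol(gs)
  border <- rbind(cbind(1L, seq_len(nc)), cbind(nr, seq_len(nc)),
                  cbind(seq.int(2L, max(2L, nr - 1L)), 1L),
                  cbind(seq.int(2L, max(2L, nr - 1L)), nc))
  g <- gs[border]
  keep <- border[g <= background_gray, , drop = FALSE]
  data.frame(row = keep[, 1L], col = keep[, 2L],
             label = rep("background", nrow(keep)))
}

#' @export
print.rw_result <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("random-walker contouring result: %d slices x %d x %d\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  processed slices: %d; ROI rows %d..%d cols %d..%d\n",
              nrow(x$log), x$roi$row_min, x$roi$row_max, x$roi$col_min,
              x$roi$col_max))
  tab <- table(factor(category_name(as.integer(x$labels)),
                      levels = rw_categories()))
  cat("  voxels per category:\n")
  for (n in names(tab)) cat(sprintf("    %-12s %d\n", n, tab[[n]]))
  invisible(x)
}
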
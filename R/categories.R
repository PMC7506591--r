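#' Segmentation categories
#'
#' The six anatomical categories contoured by the pipeline plus the implicit
#' `background` label (air outside the body). The order of this vector is the
#' fixed label-priority order used to break exact probability ties in
#' [assign_labels()]: earlier wins. Label maps store the integer position in
#' this vector (1 = body, ..., 7 = background).
#'
#' @return Character vector of the seven category names in priority order.
#' @export
#' @examples
#' rw_categories()
rw_categories <- function() {
  c("body", "lungs", "airway", "heart", "spinal_cord", "gtv", "background")
}

#' @rdname rw_categories
#' @export
rw_background_code <- function() 7L

category_code <- function(label) {
  code <- match(label, rw_categories())
  if (anyNA(code)) {
    stop("unknown category label(s): ",
         paste(unique(label[is.na(code)]), collapse = ", "))
  }
  code
}

category_name <- function(code) rw_categories()[code]

## deterministic per-(slice, category, component) stream seed, < 2^31
derive_seed <- function(base_seed, slice = 0L, cat = 0L, comp = 0L) {
  as.integer((as.double(base_seed) * 2654435.0 + slice * 7919 + cat * 131 +
                comp * 17 + 1) %% 2147483629)
}

## evaluate expr under a local RNG seed without disturbing the caller's stream
with_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
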
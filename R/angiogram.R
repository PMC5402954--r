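#' En-face angiogram object
#'
#' Container for a single-channel en-face OCTA flow image of one eye and one
#' retinal slab. Intensities are arbitrary flow-signal units; the physical
#' field of view (default 3 mm, the fovea-centered macular scan) fixes the
#' pixel size in mm.
#'
#' @param pixels numeric matrix of finite, non-negative intensities
#'   (rows = image rows, origin top-left).
#' @param fov_mm physical width of the square field of view in mm.
#' @param layer retinal slab label: `"NS-RL"` (nonsegmented whole retina),
#'   `"SRL"` (superficial) or `"DRL"` (deep).
#'
#' @return An object of class `enface_angiogram`: a list with elements
#'   `pixels`, `fov_mm`, `layer`.
#' @examples
#' a <- enface_angiogram(matrix(runif(64 * 64), 64), fov_mm = 3, layer = "SRL")
#' pixel_size_mm(a)
#' @export
enface_angiogram <- function(pixels, fov_mm = 3, layer = c("NS-RL", "SRL", "DRL")) {
  layer <- match.arg(layer)
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty numeric matrix", call. = FALSE)
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("angiogram intensities must be finite (no NA/NaN/Inf)", call. = FALSE)
  if (any(pixels < 0))
    stop("angiogram intensities must be non-negative", call. = FALSE)
  if (!is.numeric(fov_mm) || length(fov_mm) != 1L || fov_mm <= 0)
    stop("`fov_mm` must be a positive scalar", call. = FALSE)
  structure(list(pixels = pixels, fov_mm = as.numeric(fov_mm), layer = layer),
            class = "enface_angiogram")
}

#' @rdname enface_angiogram
#' @param x an `enface_angiogram`.
#' @export
pixel_size_mm <- function(x) {
  stopifnot(inherits(x, "enface_angiogram"))
  x$fov_mm / ncol(x$pixels)
}

#' @export
print.enface_angiogram <- function(x, ...) {
  cat(sprintf("<enface_angiogram> %d x %d px, %.2f mm field, layer %s\n",
              nrow(x$pixels), ncol(x$pixels), x$fov_mm, x$layer))
  invisible(x)
}

#' @export
dim.enface_angiogram <- function(x) dim(x$pixels)

# internal: coerce logical matrix inputs defensively
assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask) || length(mask) == 0L)
    stop(sprintf("`%s` must be a non-empty logical matrix", arg), call. = FALSE)
  if (anyNA(mask))
    stop(sprintf("`%s` contains NA", arg), call. = FALSE)
  invisible(mask)
}

#' Binary vessel map and skeleton containers
#'
#' `binary_vessel_map()` wraps a boolean perfusion mask together with the
#' threshold that produced it; `skeleton_map()` wraps a one-pixel-wide
#' centerline mask. Both are thin S3 records so downstream metrics can check
#' provenance (matching dimensions) cheaply.
#'
#' @param mask logical matrix; `TRUE` = vessel.
#' @param threshold_used the global threshold (original intensity units) that
#'   produced the mask, or `NA` when the mask was not produced by
#'   thresholding (e.g. ground truth).
#' @return `binary_vessel_map`: list with `mask`, `threshold_used`;
#'   `skeleton_map`: list with `mask`.
#' @export
binary_vessel_map <- function(mask, threshold_used = NA_real_) {
  assert_mask(mask)
  structure(list(mask = mask, threshold_used = as.numeric(threshold_used)),
            class = "binary_vessel_map")
}

#' @rdname binary_vessel_map
#' @export
skeleton_map <- function(mask) {
  assert_mask(mask)
  structure(list(mask = mask), class = "skeleton_map")
}

#' @export
print.binary_vessel_map <- function(x, ...) {
  cat(sprintf("<binary_vessel_map> %d x %d px, %d vessel px (%.1f%%), threshold %.4g\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask), x$threshold_used))
  invisible(x)
}

#' @export
print.skeleton_map <- function(x, ...) {
  cat(sprintf("<skeleton_map> %d x %d px, %d skeleton px\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

# internal: accept raw logical matrix, binary_vessel_map or skeleton_map
as_mask <- function(x, arg = "x") {
  if (inherits(x, "binary_vessel_map") || inherits(x, "skeleton_map")) x$mask
  else assert_mask(x, arg)
}
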
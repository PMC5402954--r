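#' Binarize an en-face angiogram
#'
#' Classifies each pixel as perfused (vessel) or background. The default
#' chain equalizes the background with a white top-hat (grayscale opening
#' subtracted from the image, removing slowly varying background while
#' keeping thin bright vessels) and then applies a global Otsu threshold.
#' Two alternatives are exposed: a global mean + k*SD threshold and a local
#' adaptive (moving-average) threshold, so the chain can be swapped to match
#' other published pipelines.
#'
#' The returned `threshold_used` is on the scale of the (possibly top-hat
#' filtered) image actually thresholded, mapped back to original intensity
#' units.
#'
#' @param angiogram an [enface_angiogram()].
#' @param method `"tophat-otsu"` (default), `"otsu"`, `"mean-sd"`, or
#'   `"adaptive"`.
#' @param tophat_radius radius (px) of the disc structuring element for the
#'   white top-hat; should exceed the widest vessel half-width.
#' @param k multiplier for `"mean-sd"` (threshold = mean + k * SD).
#' @param window half-width (px) of the moving-average window for
#'   `"adaptive"`.
#' @param offset offset subtracted from the local mean for `"adaptive"`, as a
#'   fraction of the intensity range.
#'
#' @return A [binary_vessel_map()] with the same dimensions as the input.
#' @details A constant image has no separable intensity modes and raises a
#'   degenerate-image error rather than returning an arbitrary mask: silently
#'   passing empty or full masks downstream would corrupt cohort statistics.
#' @examples
#' px <- matrix(10, 64, 64); px[20:22, ] <- 200
#' bv <- binarize(enface_angiogram(px))
#' sum(bv$mask) == 3 * 64
#' @export
binarize <- function(angiogram,
                     method = c("tophat-otsu", "otsu", "mean-sd", "adaptive"),
                     tophat_radius = 15, k = 1, window = 25, offset = 0.02) {
  method <- match.arg(method)
  stopifnot(inherits(angiogram, "enface_angiogram"))
  px <- angiogram$pixels
  rng <- range(px)
  if (rng[1] == rng[2])
    stop("degenerate image: constant intensity, no separable modes", call. = FALSE)

  # work on a [0,1] copy; remember the affine map to report thresholds in
  # original units
  scl <- rng[2] - rng[1]
  img <- (px - rng[1]) / scl

  if (method %in% c("tophat-otsu", "adaptive")) {
    brush <- EBImage::makeBrush(2L * as.integer(tophat_radius) + 1L, shape = "disc")
    filtered <- EBImage::whiteTopHat(EBImage::Image(img), brush)
    img <- pmin(pmax(EBImage::imageData(filtered), 0), 1)
  }

  if (method %in% c("tophat-otsu", "otsu")) {
    if (max(img) == min(img))
      stop("degenerate image: constant after background equalization", call. = FALSE)
    thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1), levels = 256L)
    mask <- img > thr
  } else if (method == "mean-sd") {
    thr <- mean(img) + k * stats::sd(img)
    mask <- img > thr
  } else { # adaptive: local moving-average threshold
    w <- 2L * as.integer(window) + 1L
    local_mean <- EBImage::imageData(
      EBImage::filter2(EBImage::Image(img), matrix(1 / w^2, w, w)))
    mask <- img > (local_mean + offset)
    thr <- NA_real_
  }

  binary_vessel_map(matrix(as.logical(mask), nrow(px)),
                    threshold_used = if (is.na(thr)) NA_real_ else thr * scl + rng[1])
}

#' Dice overlap between two binary masks
#'
#' @param a,b logical matrices (or mask objects) of equal dimensions.
#' @return Dice coefficient `2|A&B| / (|A|+|B|)`; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  a <- as_mask(a, "a"); b <- as_mask(b, "b")
  if (!identical(dim(a), dim(b))) stop("mask dimensions differ", call. = FALSE)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
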
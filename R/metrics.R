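#' Vessel density, skeletal density and vessel diameter index
#'
#' The three density-type parameters of the quantification:
#' \describe{
#'   \item{`vessel_density` (VD)}{fraction of the image area with detectable
#'     perfusion, i.e. set pixels of the binarized map over total pixels
#'     (0-1 scale; about 0.43 for a healthy macula).}
#'   \item{`skeletal_density` (SD)}{fraction of the image area occupied by
#'     the one-pixel-wide skeleton; since every skeleton pixel contributes
#'     unit length, SD proxies total vessel length independent of caliber.}
#'   \item{`vessel_diameter_index` (VDI)}{vessel pixel count divided by
#'     skeleton pixel count, i.e. average vessel caliber in pixels;
#'     algebraically VD / SD.}
#' }
#'
#' @param vessels a [binary_vessel_map()] or logical matrix.
#' @param skeleton a [skeleton_map()] or logical matrix derived from
#'   `vessels`; must be non-empty for VDI.
#' @return A single numeric value.
#' @examples
#' m <- matrix(FALSE, 20, 60); m[8:12, 5:55] <- TRUE
#' sk <- skeletonize(m)
#' vessel_diameter_index(m, sk)  # ~5 px for a 5-px-wide bar
#' @export
vessel_density <- function(vessels) {
  m <- as_mask(vessels, "vessels")
  mean(m)
}

#' @rdname vessel_density
#' @export
skeletal_density <- function(skeleton) {
  m <- as_mask(skeleton, "skeleton")
  mean(m)
}

#' @rdname vessel_density
#' @export
vessel_diameter_index <- function(vessels, skeleton) {
  v <- as_mask(vessels, "vessels")
  s <- as_mask(skeleton, "skeleton")
  if (!identical(dim(v), dim(s)))
    stop("vessel and skeleton dimensions differ", call. = FALSE)
  if (!any(s)) stop("no vessels: empty skeleton, VDI undefined", call. = FALSE)
  if (any(s & !v))
    stop("skeleton is not a subset of the vessel mask", call. = FALSE)
  sum(v) / sum(s)
}

#' Quantify one angiogram
#'
#' Runs the full per-image chain binarize -> skeletonize -> {FD, VD, SD,
#' VDI} and returns the four parameters together with audit fields (the
#' global threshold and the box-count fit quality). Identical input and
#' configuration give identical output.
#'
#' @param angiogram an [enface_angiogram()].
#' @param ... binarization settings passed to [binarize()].
#' @param box_sizes optional box-size override for [fractal_dimension()].
#' @return A `metric_set`: list with `fd`, `vd`, `sd`, `vdi`,
#'   `threshold_used`, `box_fit_r2`. Invariants: `0 <= sd <= vd <= 1`,
#'   `vdi == vd / sd`, `0 <= fd <= 2`.
#' @export
quantify <- function(angiogram, ..., box_sizes = NULL) {
  bv <- binarize(angiogram, ...)
  sk <- skeletonize(bv)
  if (!any(sk$mask))
    stop("no vessels detected after binarization", call. = FALSE)
  fd <- fractal_dimension(sk, box_sizes = box_sizes)
  metric_set(fd = fd$fd,
             vd = vessel_density(bv),
             sd = skeletal_density(sk),
             vdi = vessel_diameter_index(bv, sk),
             threshold_used = bv$threshold_used,
             box_fit_r2 = fd$r_squared)
}

#' @rdname quantify
#' @param fd,vd,sd,vdi,threshold_used,box_fit_r2 components of the set.
#' @export
metric_set <- function(fd, vd, sd, vdi, threshold_used = NA_real_,
                       box_fit_r2 = NA_real_) {
  if (!(sd >= 0 && vd >= sd && vd <= 1))
    stop("invalid metric set: need 0 <= SD <= VD <= 1", call. = FALSE)
  if (sd > 0 && abs(vdi * sd - vd) > 1e-10 * max(1, vd))
    stop("invalid metric set: VDI * SD must equal VD", call. = FALSE)
  structure(list(fd = fd, vd = vd, sd = sd, vdi = vdi,
                 threshold_used = threshold_used, box_fit_r2 = box_fit_r2),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> FD %.4f  VD %.4f  SD %.4f  VDI %.3f\n",
              x$fd, x$vd, x$sd, x$vdi))
  invisible(x)
}

#' @export
as.data.frame.metric_set <- function(x, ...) {
  data.frame(fd = x$fd, vd = x$vd, sd = x$sd, vdi = x$vdi,
             threshold_used = x$threshold_used, box_fit_r2 = x$box_fit_r2)
}
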
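# Rasterization of vessel networks into en-face angiograms.

# paint all segments into a logical mask: a pixel is set iff its center lies
# within half the stroke width of the sampled centerline (deterministic,
# resolution-consistent). Sub-pixel calibers are clamped to one pixel.
rasterize_segments <- function(segments, fov_mm, size_px, warn_clamp = FALSE) {
  mask <- matrix(FALSE, size_px, size_px)
  if (length(segments) == 0L) return(mask)
  px_mm <- fov_mm / size_px
  clamped <- FALSE
  for (seg in segments) {
    # pixel coordinates of the polyline (pixel centers at i - 0.5)
    cx <- seg$x / px_mm + 0.5
    cy <- seg$y / px_mm + 0.5
    r <- (seg$width_um / 1000) / px_mm / 2
    if (r < 0.5) { r <- 0.5; clamped <- TRUE }
    # resample the polyline at ~0.5 px steps
    dx <- diff(cx); dy <- diff(cy)
    steps <- pmax(1L, ceiling(sqrt(dx^2 + dy^2) / 0.5))
    sx <- unlist(lapply(seq_along(dx), function(i)
      cx[i] + dx[i] * seq(0, 1, length.out = steps[i] + 1L)))
    sy <- unlist(lapply(seq_along(dy), function(i)
      cy[i] + dy[i] * seq(0, 1, length.out = steps[i] + 1L)))
    ri <- as.integer(round(sx)); ci <- as.integer(round(sy))
    pts <- unique(cbind(ri, ci))
    # disc offsets for this caliber
    w <- as.integer(ceiling(r))
    off <- expand.grid(dr = -w:w, dc = -w:w)
    off <- off[off$dr^2 + off$dc^2 <= r^2 + 1e-9, , drop = FALSE]
    rr <- rep(pts[, 1L], each = nrow(off)) + off$dr
    cc <- rep(pts[, 2L], each = nrow(off)) + off$dc
    ok <- rr >= 1L & rr <= size_px & cc >= 1L & cc <= size_px
    mask[cbind(rr[ok], cc[ok])] <- TRUE
  }
  if (clamped && warn_clamp)
    warning("segment caliber below one pixel; clamped to one pixel")
  mask
}

#' Render a vessel network as an en-face angiogram
#'
#' Rasterizes each segment as a stroke of thickness `width_um` converted to
#' pixels, then applies the noise model: vessel pixels get a high mean
#' intensity with multiplicative (log-normal) speckle, background pixels a
#' low mean with additive Gaussian noise, all clipped to [0, 1]. The
#' noiseless stroke mask is returned as ground truth. With all noise
#' amplitudes zero the image contains exactly two intensity levels.
#'
#' @param network a `vessel_network` from [grow_network()].
#' @param image_size_px square image side in pixels (>= 128).
#' @param noise list with `vessel_mean`, `speckle_sd` (log-scale SD of the
#'   multiplicative speckle), `bg_mean`, `bg_sd`.
#' @param blur_sigma_px optional Gaussian blur (px) applied to the noisy
#'   image, used to emulate edema-related degradation.
#' @param layer layer label recorded on the output angiogram.
#' @param seed integer seed for the noise draws.
#' @return List with `angiogram` (an [enface_angiogram()]) and `truth`
#'   (a [binary_vessel_map()] of the noiseless strokes).
#' @export
render_angiogram <- function(network, image_size_px = 1024,
                             noise = default_noise(), blur_sigma_px = 0,
                             layer = "NS-RL", seed = 1L) {
  stopifnot(inherits(network, "vessel_network"))
  if (image_size_px < 128) stop("image_size_px must be >= 128", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mask <- rasterize_segments(network$segments, network$fov_mm, image_size_px,
                             warn_clamp = TRUE)
  img <- compose_intensity(mask, noise)
  if (blur_sigma_px > 0)
    img <- pmin(pmax(EBImage::imageData(
      EBImage::gblur(EBImage::Image(img), sigma = blur_sigma_px)), 0), 1)
  list(angiogram = enface_angiogram(img, fov_mm = network$fov_mm, layer = layer),
       truth = binary_vessel_map(mask))
}

# vessel/background intensity model shared by single- and multi-layer paths
compose_intensity <- function(mask, noise) {
  img <- matrix(noise$bg_mean, nrow(mask), ncol(mask))
  nbg <- sum(!mask)
  if (noise$bg_sd > 0)
    img[!mask] <- img[!mask] + stats::rnorm(nbg, 0, noise$bg_sd)
  nv <- sum(mask)
  if (noise$speckle_sd > 0) {
    img[mask] <- noise$vessel_mean *
      exp(stats::rnorm(nv, -noise$speckle_sd^2 / 2, noise$speckle_sd))
  } else img[mask] <- noise$vessel_mean
  pmin(pmax(img, 0), 1)
}

#' @rdname render_angiogram
#' @export
default_noise <- function() {
  list(vessel_mean = 0.75, speckle_sd = 0.30, bg_mean = 0.12, bg_sd = 0.04)
}
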
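# Synthetic macular vascular networks.
#
# A network is a list of segments, each a polyline in mm with a caliber in
# micrometers. Trunk arterioles/venules enter from the field edge and branch
# into smaller vessels; a space-filling capillary mesh is then grown until
# the rasterized coverage reaches a target fraction, with a capillary-free
# disk (the foveal avascular zone) kept clear at the field center.

#' Specification of a synthetic vascular network
#'
#' @param n_trunks number of large vessels entering from the field edge.
#' @param branch_probability per-step probability that a growing vessel
#'   spawns a daughter branch.
#' @param tortuosity standard deviation (radians) of the per-step heading
#'   perturbation; larger values give wigglier vessels.
#' @param coverage target fraction of the field covered by vessels after
#'   rasterization (closed loop: growth stops when the rendered mask reaches
#'   it). Must lie in (0, 0.9]; healthy macular plexus is about 0.4.
#' @param trunk_width_um,branch_width_um,capillary_width_um caliber ranges
#'   (min, max) in micrometers for each vessel class.
#' @param faz_radius_mm radius of the foveal avascular zone; no centerline
#'   enters this disk. Must be smaller than half the field of view.
#' @param fov_mm field of view in mm (square).
#' @param coverage_check_px raster size used for the closed-loop coverage
#'   measurement during growth.
#' @return A list of class `vascular_network_spec`.
#' @export
vascular_network_spec <- function(n_trunks = 5,
                                  branch_probability = 0.08,
                                  tortuosity = 0.25,
                                  coverage = 0.40,
                                  trunk_width_um = c(25, 35),
                                  branch_width_um = c(14, 22),
                                  capillary_width_um = c(8, 13),
                                  faz_radius_mm = 0.3,
                                  fov_mm = 3,
                                  coverage_check_px = 256) {
  if (!(coverage > 0 && coverage <= 0.9))
    stop("coverage target must lie in (0, 0.9]", call. = FALSE)
  if (faz_radius_mm <= 0 || faz_radius_mm >= fov_mm / 2)
    stop("faz_radius_mm must be positive and below half the field of view", call. = FALSE)
  structure(list(n_trunks = n_trunks, branch_probability = branch_probability,
                 tortuosity = tortuosity, coverage = coverage,
                 trunk_width_um = trunk_width_um,
                 branch_width_um = branch_width_um,
                 capillary_width_um = capillary_width_um,
                 faz_radius_mm = faz_radius_mm, fov_mm = fov_mm,
                 coverage_check_px = coverage_check_px),
            class = "vascular_network_spec")
}

# walk one vessel from (x, y) with given heading; steps of `ds` mm, heading
# jitter `tort`, reflected away from the FAZ disk and stopped at the border.
walk_polyline <- function(x, y, heading, length_mm, ds, tort, fov, faz) {
  n_steps <- max(2L, ceiling(length_mm / ds))
  xs <- numeric(n_steps + 1L); ys <- numeric(n_steps + 1L)
  xs[1] <- x; ys[1] <- y
  cx <- fov / 2; cy <- fov / 2
  k <- 1L
  for (i in seq_len(n_steps)) {
    heading <- heading + stats::rnorm(1, 0, tort)
    nx <- xs[k] + ds * cos(heading)
    ny <- ys[k] + ds * sin(heading)
    # steer away from the avascular zone
    if (sqrt((nx - cx)^2 + (ny - cy)^2) < faz) {
      away <- atan2(ys[k] - cy, xs[k] - cx)
      heading <- away + stats::rnorm(1, 0, 0.3)
      nx <- xs[k] + ds * cos(heading)
      ny <- ys[k] + ds * sin(heading)
      if (sqrt((nx - cx)^2 + (ny - cy)^2) < faz) break
    }
    if (nx < 0 || nx > fov || ny < 0 || ny > fov) break
    k <- k + 1L
    xs[k] <- nx; ys[k] <- ny
  }
  if (k < 2L) return(NULL)
  list(x = xs[1:k], y = ys[1:k], heading = heading)
}

new_segment <- function(poly, width_um, generation, type) {
  list(x = poly$x, y = poly$y, width_um = width_um,
       generation = generation, type = type)
}

#' Grow a synthetic vascular network
#'
#' Grows stochastic branching trees from edge trunks, then fills with a
#' capillary mesh until the rasterized vessel coverage reaches the target in
#' `spec`. Fully deterministic for a fixed seed.
#'
#' @param spec a [vascular_network_spec()].
#' @param seed integer seed for all randomness in the growth.
#' @return An object of class `vessel_network`: list with `segments` (each
#'   with polyline `x`, `y` in mm, `width_um`, `generation`, `type`) and
#'   `fov_mm`.
#' @examples
#' net <- grow_network(vascular_network_spec(coverage = 0.3), seed = 1)
#' length(net$segments)
#' @export
grow_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "vascular_network_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fov <- spec$fov_mm; faz <- spec$faz_radius_mm
  segments <- list()

  runif_rng <- function(r) stats::runif(1, r[1], r[2])

  # trunks enter from the four edges, heading inward
  for (t in seq_len(spec$n_trunks)) {
    edge <- (t - 1L) %% 4L
    pos <- stats::runif(1, 0.1, 0.9) * fov
    start <- switch(edge + 1L,
                    c(pos, 0, pi / 2), c(pos, fov, -pi / 2),
                    c(0, pos, 0), c(fov, pos, pi))
    heading <- start[3] + stats::runif(1, -0.5, 0.5)
    poly <- walk_polyline(start[1], start[2], heading, 1.4 * fov, 0.05,
                          spec$tortuosity * 0.5, fov, faz)
    if (is.null(poly)) next
    segments[[length(segments) + 1L]] <-
      new_segment(poly, runif_rng(spec$trunk_width_um), 0L, "trunk")
    # daughter branches along the trunk
    npts <- length(poly$x)
    for (i in seq(2, npts - 1)) {
      if (stats::runif(1) < spec$branch_probability) {
        bh <- atan2(poly$y[i + 1] - poly$y[i], poly$x[i + 1] - poly$x[i]) +
          sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.2)
        bp <- walk_polyline(poly$x[i], poly$y[i], bh,
                            stats::runif(1, 0.3, 0.8) * fov, 0.05,
                            spec$tortuosity, fov, faz)
        if (!is.null(bp))
          segments[[length(segments) + 1L]] <-
            new_segment(bp, runif_rng(spec$branch_width_um), 1L, "branch")
      }
    }
  }

  # capillary mesh grown closed-loop against rasterized coverage
  npx <- spec$coverage_check_px
  mask <- rasterize_segments(segments, fov, npx)
  batch <- 40L
  max_caps <- 40000L
  n_caps <- 0L
  while (mean(mask) < spec$coverage) {
    new_caps <- vector("list", batch)
    kept <- 0L
    for (b in seq_len(batch)) {
      repeat {
        sx <- stats::runif(1, 0.02, 0.98) * fov
        sy <- stats::runif(1, 0.02, 0.98) * fov
        if (sqrt((sx - fov / 2)^2 + (sy - fov / 2)^2) >= faz) break
      }
      cp <- walk_polyline(sx, sy, stats::runif(1, 0, 2 * pi),
                          stats::runif(1, 0.12, 0.35), 0.03,
                          spec$tortuosity * 2, fov, faz)
      if (!is.null(cp)) {
        kept <- kept + 1L
        new_caps[[kept]] <- new_segment(cp, runif_rng(spec$capillary_width_um),
                                        2L, "capillary")
      }
    }
    new_caps <- new_caps[seq_len(kept)]
    mask <- mask | rasterize_segments(new_caps, fov, npx)
    segments <- c(segments, new_caps)
    n_caps <- n_caps + kept
    if (n_caps > max_caps)
      stop("coverage target unreachable within the segment budget", call. = FALSE)
  }
  structure(list(segments = segments, fov_mm = fov), class = "vessel_network")
}

#' @export
print.vessel_network <- function(x, ...) {
  types <- vapply(x$segments, `[[`, "", "type")
  cat(sprintf("<vessel_network> %d segments (%d trunk, %d branch, %d capillary), %.1f mm field\n",
              length(x$segments), sum(types == "trunk"), sum(types == "branch"),
              sum(types == "capillary"), x$fov_mm))
  invisible(x)
}

#' Specification of an occlusion pathology
#'
#' Emulates the capillary nonperfusion patterns of retinal venous occlusion:
#' branch occlusion (BRVO) drops capillaries inside an angular wedge (the
#' sector drained by the occluded branch vein), central occlusion (CRVO)
#' drops capillaries diffusely, and surviving vessels dilate.
#'
#' @param rvo_type `"none"`, `"BRVO"` or `"CRVO"`.
#' @param wedge_center_deg,wedge_extent_deg the affected sector (BRVO only;
#'   angles measured from the field center, degrees).
#' @param dropout_fraction probability that an eligible capillary segment is
#'   removed.
#' @param survivor_dilation_factor multiplier (>= 1) applied to the caliber
#'   of every surviving segment.
#' @param edema_blur_sigma_px Gaussian blur applied at render time to mimic
#'   edema-related signal degradation (0 = none).
#' @return A list of class `pathology_spec`.
#' @export
pathology_spec <- function(rvo_type = c("none", "BRVO", "CRVO"),
                           wedge_center_deg = NULL, wedge_extent_deg = NULL,
                           dropout_fraction = 0,
                           survivor_dilation_factor = 1,
                           edema_blur_sigma_px = 0) {
  rvo_type <- match.arg(rvo_type)
  if (rvo_type == "BRVO" &&
      (is.null(wedge_center_deg) || is.null(wedge_extent_deg)))
    stop("BRVO requires wedge_center_deg and wedge_extent_deg", call. = FALSE)
  if (rvo_type != "BRVO" &&
      !(is.null(wedge_center_deg) && is.null(wedge_extent_deg)))
    stop("wedge fields are only meaningful for BRVO", call. = FALSE)
  if (dropout_fraction < 0 || dropout_fraction > 1)
    stop("dropout_fraction must lie in [0, 1]", call. = FALSE)
  if (survivor_dilation_factor < 1)
    stop("survivor_dilation_factor must be >= 1", call. = FALSE)
  structure(list(rvo_type = rvo_type, wedge_center_deg = wedge_center_deg,
                 wedge_extent_deg = wedge_extent_deg,
                 dropout_fraction = dropout_fraction,
                 survivor_dilation_factor = survivor_dilation_factor,
                 edema_blur_sigma_px = edema_blur_sigma_px),
            class = "pathology_spec")
}

#' Apply an occlusion pathology to a network
#'
#' BRVO removes each capillary whose midpoint lies inside the wedge with
#' probability `dropout_fraction` and leaves the opposite hemifield
#' untouched; CRVO removes capillaries globally with the same probability.
#' Trunks and branches are never removed. All surviving segments have their
#' caliber multiplied by `survivor_dilation_factor` (capillary dilation of
#' the surviving bed).
#'
#' @param network a `vessel_network`.
#' @param spec a [pathology_spec()].
#' @param seed integer seed for the dropout draws.
#' @return The modified `vessel_network`.
#' @export
apply_pathology <- function(network, spec, seed = 1L) {
  stopifnot(inherits(network, "vessel_network"), inherits(spec, "pathology_spec"))
  if (spec$rvo_type == "none" && spec$survivor_dilation_factor == 1)
    return(network)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fov <- network$fov_mm
  keep <- vapply(network$segments, function(seg) {
    if (seg$type != "capillary" || spec$rvo_type == "none") return(TRUE)
    if (spec$rvo_type == "BRVO") {
      mid <- ceiling(length(seg$x) / 2)
      ang <- atan2(seg$y[mid] - fov / 2, seg$x[mid] - fov / 2) * 180 / pi
      d <- ((ang - spec$wedge_center_deg + 180) %% 360) - 180
      if (abs(d) > spec$wedge_extent_deg / 2) return(TRUE)
    }
    stats::runif(1) >= spec$dropout_fraction
  }, logical(1))
  segs <- network$segments[keep]
  if (spec$survivor_dilation_factor != 1)
    segs <- lapply(segs, function(seg) {
      seg$width_um <- seg$width_um * spec$survivor_dilation_factor
      seg
    })
  structure(list(segments = segs, fov_mm = fov), class = "vessel_network")
}

# save/restore the global RNG state so generator functions are pure
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
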
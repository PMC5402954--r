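test_that("network growth is deterministic and respects the avascular zone", {
  spec <- vascular_network_spec(coverage = 0.3, faz_radius_mm = 0.3,
                                coverage_check_px = 192)
  n1 <- grow_network(spec, seed = 5)
  n2 <- grow_network(spec, seed = 5)
  expect_identical(n1, n2)
  n3 <- grow_network(spec, seed = 6)
  expect_false(identical(n1, n3))

  pts <- do.call(rbind, lapply(n1$segments, function(s) cbind(s$x, s$y)))
  d <- sqrt((pts[, 1] - 1.5)^2 + (pts[, 2] - 1.5)^2)
  expect_gte(min(d), 0.3)
})

test_that("closed-loop growth hits the coverage target", {
  spec <- vascular_network_spec(coverage = 0.40, coverage_check_px = 256)
  net <- grow_network(spec, seed = 17)
  r <- suppressWarnings(render_angiogram(net, 256, seed = 18))
  vd_truth <- vessel_density(r$truth)
  expect_lt(abs(vd_truth - 0.40), 0.03)
  vd_bin <- vessel_density(binarize(r$angiogram))
  expect_lt(abs(vd_bin - 0.40), 0.03)
})

test_that("spec validation rejects impossible settings", {
  expect_error(vascular_network_spec(coverage = 0.95), "coverage")
  expect_error(vascular_network_spec(faz_radius_mm = 2), "faz_radius_mm")
  expect_error(pathology_spec("BRVO", dropout_fraction = 0.5), "wedge")
  expect_error(pathology_spec("CRVO", wedge_center_deg = 0,
                              wedge_extent_deg = 90, dropout_fraction = 0.5),
               "only meaningful")
  expect_error(pathology_spec("CRVO", dropout_fraction = 1.5), "dropout_fraction")
})

test_that("branch-occlusion dropout is confined to the wedge", {
  spec <- vascular_network_spec(coverage = 0.3, coverage_check_px = 192)
  net <- grow_network(spec, seed = 8)
  path <- pathology_spec("BRVO", wedge_center_deg = 0, wedge_extent_deg = 180,
                         dropout_fraction = 1)
  net2 <- apply_pathology(net, path, seed = 9)
  midang <- function(seg) {
    i <- ceiling(length(seg$x) / 2)
    atan2(seg$y[i] - 1.5, seg$x[i] - 1.5) * 180 / pi
  }
  key <- function(seg) paste(seg$type, seg$x[1], seg$y[1])
  kept <- vapply(net2$segments, key, "")
  for (seg in net$segments) {
    if (seg$type != "capillary") next
    a <- ((midang(seg) + 180) %% 360) - 180
    inside <- abs(a) <= 90
    if (inside) expect_false(key(seg) %in% kept)
    else expect_true(key(seg) %in% kept)
  }
})

test_that("diffuse dropout halves skeletal density and dilation raises VDI", {
  spec <- vascular_network_spec(n_trunks = 2, branch_probability = 0.02,
                                coverage = 0.20, coverage_check_px = 256)
  net <- grow_network(spec, seed = 3)
  m0 <- octaquant:::rasterize_segments(net$segments, 3, 256)
  sk0 <- skeletonize(m0)

  halved <- apply_pathology(net, pathology_spec("CRVO", dropout_fraction = 0.5),
                            seed = 4)
  mh <- octaquant:::rasterize_segments(halved$segments, 3, 256)
  ratio <- skeletal_density(skeletonize(mh)) / skeletal_density(sk0)
  expect_gt(ratio, 0.4)
  expect_lt(ratio, 0.6)

  dilated <- apply_pathology(net, pathology_spec("none",
                                                 survivor_dilation_factor = 1.5),
                             seed = 4)
  md <- octaquant:::rasterize_segments(dilated$segments, 3, 256)
  vdi0 <- vessel_diameter_index(m0, sk0)
  vdid <- vessel_diameter_index(md, skeletonize(md))
  expect_gt(vdid, vdi0)
})

test_that("rendering: stroke thickness, noise model and determinism", {
  seg <- list(list(x = seq(0.3, 2.7, length.out = 50), y = rep(1.5, 50),
                   width_um = 30, generation = 0L, type = "trunk"))
  m <- octaquant:::rasterize_segments(seg, 3, 1024)
  th <- rowSums(m); th <- th[th > 0]
  th <- th[5:(length(th) - 5)]  # away from the rounded ends
  expect_true(all(th >= 9 & th <= 11))  # 30 um at ~2.93 um/px -> 10 +/- 1

  net <- grow_network(vascular_network_spec(coverage = 0.25,
                                            coverage_check_px = 192), seed = 2)
  r0 <- suppressWarnings(render_angiogram(
    net, 192, noise = list(vessel_mean = 0.8, speckle_sd = 0,
                           bg_mean = 0.1, bg_sd = 0), seed = 1))
  expect_equal(sort(unique(as.vector(r0$angiogram$pixels))), c(0.1, 0.8))
  expect_identical(r0$truth$mask, r0$angiogram$pixels == 0.8)

  ra <- suppressWarnings(render_angiogram(net, 192, seed = 10))
  rb <- suppressWarnings(render_angiogram(net, 192, seed = 10))
  expect_identical(ra$angiogram$pixels, rb$angiogram$pixels)

  thin <- list(list(x = c(1, 2), y = c(1, 1), width_um = 2,
                    generation = 0L, type = "capillary"))
  tiny_net <- structure(list(segments = thin, fov_mm = 3), class = "vessel_network")
  expect_warning(render_angiogram(tiny_net, 128, seed = 1), "clamped")
  expect_error(render_angiogram(net, 64), ">= 128")
})
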
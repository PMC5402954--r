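test_that("vessel and skeletal density are exact pixel fractions", {
  full <- matrix(TRUE, 10, 10)
  expect_equal(vessel_density(full), 1.0)
  checker <- matrix(rep(c(TRUE, FALSE), 50), 10)
  expect_equal(vessel_density(checker), 0.5)
  set.seed(4)
  m <- matrix(FALSE, 100, 100); m[sample(1e4, 4321)] <- TRUE
  expect_equal(vessel_density(m), 0.4321)

  row1 <- matrix(FALSE, 100, 100); row1[50, ] <- TRUE
  expect_equal(skeletal_density(row1), 0.01)
  expect_equal(skeletal_density(matrix(FALSE, 5, 5)), 0.0)
})

test_that("VDI equals VD/SD and is 1 for one-pixel-wide vessels", {
  line <- matrix(FALSE, 20, 50); line[10, 5:45] <- TRUE
  expect_equal(vessel_diameter_index(line, line), 1.0)

  for (s in 1:6) {
    m <- random_network_mask(s)
    sk <- skeletonize(m)
    vdi <- vessel_diameter_index(m, sk)
    expect_equal(vdi * skeletal_density(sk), vessel_density(m),
                 tolerance = 1e-12)
  }
  expect_error(vessel_diameter_index(line, matrix(FALSE, 20, 50)), "empty skeleton")
})

test_that("adding vessel pixels never decreases VD; dilation raises VDI", {
  m <- random_network_mask(2)
  vd0 <- vessel_density(m)
  m2 <- m; m2[which(!m)[1:50]] <- TRUE
  expect_gte(vessel_density(m2), vd0)

  bar <- matrix(FALSE, 30, 120); bar[14:16, 10:110] <- TRUE
  fat <- matrix(FALSE, 30, 120); fat[12:18, 10:110] <- TRUE
  vdi_thin <- vessel_diameter_index(bar, skeletonize(bar))
  vdi_fat <- vessel_diameter_index(fat, skeletonize(fat))
  expect_gt(vdi_fat, vdi_thin)
})

test_that("quantify composes the individual operations and is deterministic", {
  r <- quick_angiogram(13, size = 256)
  ms <- quantify(r$angiogram)
  bv <- binarize(r$angiogram)
  sk <- skeletonize(bv)
  fd <- fractal_dimension(sk)
  expect_equal(ms$vd, vessel_density(bv))
  expect_equal(ms$sd, skeletal_density(sk))
  expect_equal(ms$vdi, vessel_diameter_index(bv, sk))
  expect_equal(ms$fd, fd$fd)
  expect_true(ms$sd <= ms$vd && ms$vd <= 1)

  ms2 <- quantify(r$angiogram)
  expect_identical(as.data.frame(ms), as.data.frame(ms2))
})

test_that("a one-pixel grid pattern yields VDI 1 and SD == VD", {
  px <- matrix(10, 128, 128)
  px[seq(5, 124, by = 8), ] <- 200  # thin horizontal lines
  # a periodic line grid is not fractal, so the box-count fit rightly warns
  ms <- suppressWarnings(quantify(enface_angiogram(px)))
  expect_equal(ms$vdi, 1.0)
  expect_equal(ms$sd, ms$vd)
})

test_that("metric_set enforces its invariants", {
  expect_error(metric_set(fd = 1.5, vd = 0.2, sd = 0.3, vdi = 0.67), "SD <= VD")
  expect_error(metric_set(fd = 1.5, vd = 0.4, sd = 0.1, vdi = 3.0), "VDI")
  ok <- metric_set(fd = 1.5, vd = 0.4, sd = 0.1, vdi = 4.0)
  expect_s3_class(ok, "metric_set")
})
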
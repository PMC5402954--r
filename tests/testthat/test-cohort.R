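test_that("default cohort reproduces the study composition", {
  co <- generate_cohort(cohort_spec(), seed = 1)
  one_layer <- co[co$layer == "NS-RL", ]
  expect_equal(sum(one_layer$rvo_status == "control"), 26)
  expect_equal(sum(one_layer$rvo_status == "RVO" & one_layer$subject_type == "BRVO"), 20)
  expect_equal(sum(one_layer$rvo_status == "RVO" & one_layer$subject_type == "CRVO"), 14)
  expect_equal(sum(one_layer$rvo_status == "fellow"), 34)
  # affected and fellow eye of one subject are contralateral
  rvo_sub <- one_layer[one_layer$rvo_status != "control", ]
  eyes_per_sub <- tapply(rvo_sub$eye, rvo_sub$subject_id,
                         function(e) length(unique(e)))
  expect_true(all(eyes_per_sub == 2))
})

test_that("cohort generation is deterministic under the master seed", {
  s <- cohort_spec(n_control = 6, n_brvo = 4, n_crvo = 3)
  c1 <- generate_cohort(s, seed = 99)
  c2 <- generate_cohort(s, seed = 99)
  expect_identical(c1, c2)
  c3 <- generate_cohort(s, seed = 100)
  expect_false(identical(c1, c3))
})

test_that("metric columns respect the density invariants", {
  co <- generate_cohort(cohort_spec(), seed = 2)
  expect_true(all(co$sd >= 0 & co$sd <= co$vd & co$vd <= 1))
  expect_true(all(co$vdi >= 1))
  expect_true(all(co$age >= 40 & co$age <= 95))
})

test_that("control ages aggregate to the target mean across cohorts", {
  ages <- unlist(lapply(1:50, function(i) {
    co <- generate_cohort(cohort_spec(n_brvo = 0, n_crvo = 0), seed = 500 + i,
                          layers = "NS-RL")
    co$age
  }))
  expect_lt(abs(mean(ages) - 60.9), 2.0)
})

test_that("higher between-eye correlation couples fellow and affected eyes", {
  pair_cor <- function(rho, seed) {
    co <- generate_cohort(cohort_spec(n_control = 0, n_brvo = 60, n_crvo = 0,
                                      rho = rho, fellow_shift = 0),
                          seed = seed, layers = "NS-RL")
    aff <- co[co$rvo_status == "RVO", ]
    fel <- co[co$rvo_status == "fellow", ]
    fel <- fel[match(aff$subject_id, fel$subject_id), ]
    cor(aff$vd, fel$vd)
  }
  expect_gt(pair_cor(0.9, 7), pair_cor(0, 7) + 0.3)
})

test_that("empty cohorts are rejected", {
  expect_error(cohort_spec(n_control = 0, n_brvo = 0, n_crvo = 0), "empty")
  expect_error(cohort_spec(rho = 1), "rho")
})

test_that("images mode produces quantified eyes with matching ground truth", {
  s <- cohort_spec(n_control = 2, n_brvo = 1, n_crvo = 1)
  co <- suppressWarnings(generate_cohort(s, seed = 3, mode = "images",
                                         layers = c("SRL", "NS-RL"),
                                         image_size_px = 128,
                                         keep_images = TRUE))
  expect_equal(nrow(co), 6 * 2)  # 6 eyes x 2 layers
  eyes <- attr(co, "eyes")
  expect_length(eyes, 6)
  e1 <- eyes[[1]]
  expect_identical(dim(e1$SRL$truth$mask), dim(e1$SRL$angiogram$pixels))
  # nonsegmented truth is the union of the per-plexus truths
  expect_true(all(e1$SRL$truth$mask <= e1$`NS-RL`$truth$mask))
  expect_true(all(co$sd <= co$vd))
})

test_that("cohort summary matches direct arithmetic", {
  co <- generate_cohort(cohort_spec(n_control = 8, n_brvo = 5, n_crvo = 4),
                        seed = 12)
  sm <- summarize_cohort(co)
  ctrl <- co[co$rvo_status == "control" & co$layer == "NS-RL", ]
  expect_equal(sm$age_mean[sm$group == "control"], mean(ctrl$age))
  expect_equal(sm$age_sd[sm$group == "control"], sd(ctrl$age))
  expect_equal(sm$logmar_se[sm$group == "control"],
               sd(ctrl$logmar) / sqrt(nrow(ctrl)))
  expect_equal(sm$n_eyes[sm$group == "BRVO"], 5)
  expect_equal(logmar_to_snellen(0), "20/20")
})
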
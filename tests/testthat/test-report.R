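test_that("group contrasts recover the direction and ordering of the pathology", {
  co <- generate_cohort(cohort_spec(), seed = 71)
  brvo <- compare_groups(co, "NS-RL", "vd", "BRVO vs control")
  crvo <- compare_groups(co, "NS-RL", "vd", "CRVO vs control")
  expect_lt(brvo$beta, 0)
  expect_lt(crvo$beta, 0)
  expect_lt(crvo$beta, brvo$beta)  # central occlusion loses more density
  expect_true(brvo$ci_low <= brvo$beta && brvo$beta <= brvo$ci_high)
  expect_lt(brvo$p_value, 0.001)
  expect_true(is.finite(brvo$p_rank))
})

test_that("null cohorts show type-I-like behaviour of the contrast betas", {
  # no pathology: all groups drawn from the control distribution
  cal <- metric_calibration()
  ctl <- cal[cal$group == "control", c("layer", "metric", "mean", "sd")]
  for (g in c("BRVO", "CRVO")) {
    i <- match(paste(cal$layer, cal$metric)[cal$group == g],
               paste(ctl$layer, ctl$metric))
    cal$mean[cal$group == g] <- ctl$mean[i]
    cal$sd[cal$group == g] <- ctl$sd[i]
  }
  spec <- cohort_spec(fellow_shift = 0, calibration = cal)
  hits <- unlist(lapply(1:40, function(k) {
    co <- generate_cohort(spec, seed = 700 + k, layers = "NS-RL")
    unlist(lapply(c("BRVO vs control", "CRVO vs control"), function(ct)
      sapply(c("fd", "vd", "sd", "vdi"), function(m) {
        r <- compare_groups(co, "NS-RL", m, ct)
        abs(r$beta) < 2 * (r$ci_high - r$beta) / qnorm(0.975)
      })))
  }))
  expect_gte(mean(hits), 0.9)
})

test_that("contrasts with an absent group fail loudly", {
  co <- generate_cohort(cohort_spec(n_crvo = 0), seed = 72)
  expect_error(compare_groups(co, "NS-RL", "vd", "CRVO vs control"), "absent")
  expect_error(compare_groups(co, "NS-RL", "vd", "bogus vs control"), "unknown")
})

test_that("comparison and trend reports cover every cell", {
  co <- generate_cohort(cohort_spec(n_control = 10, n_brvo = 6, n_crvo = 5),
                        seed = 73)
  rep2 <- comparison_report(co)
  expect_equal(nrow(rep2), 3 * 4 * 2)  # layers x metrics x contrasts
  expect_true(all(rep2$ci_low <= rep2$beta & rep2$beta <= rep2$ci_high))

  tr <- trend_report(co, layers = "NS-RL")
  expect_equal(nrow(tr), 4 * 2)  # metrics x orderings
  expect_true(all(tr$p_asymptotic >= 0 & tr$p_asymptotic <= 1))
  # density decreases along the severity ordering
  vd_row <- tr[tr$metric == "vd" & tr$ordering == "rvo_type", ]
  expect_gt(vd_row$mean_1, vd_row$mean_3)
})

test_that("missing metric rows are dropped with a message", {
  co <- generate_cohort(cohort_spec(n_control = 8, n_brvo = 6, n_crvo = 4),
                        seed = 74, layers = "NS-RL")
  co$vd[3] <- NA
  expect_message(r <- compare_groups(co, "NS-RL", "vd", "RVO vs control"),
                 "dropping 1 rows")
  expect_true(is.finite(r$beta))
})
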
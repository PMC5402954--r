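test_that("GEE reduces to OLS with one observation per cluster", {
  set.seed(41)
  d <- data.frame(y = rnorm(50), g = rep(c("a", "b"), 25),
                  age = rnorm(50, 60, 9), id = 1:50)
  f <- fit_gee(y ~ g + age, d, id = id)
  o <- lm(y ~ g + age, d)
  expect_lt(max(abs(f$coefficients - coef(o))), 1e-8)
  # two-group mean difference with no covariates
  f2 <- fit_gee(y ~ g, d, id = id)
  expect_lt(abs(f2$coefficients[["gb"]] -
                  (mean(d$y[d$g == "b"]) - mean(d$y[d$g == "a"]))), 1e-8)
})

test_that("duplicating every cluster's observation leaves estimates unchanged", {
  set.seed(42)
  d <- data.frame(y = rnorm(30), x = rnorm(30), id = 1:30)
  f1 <- fit_gee(y ~ x, d, id = id)
  d2 <- rbind(d, d)
  f2 <- fit_gee(y ~ x, d2, id = id)
  expect_lt(max(abs(f1$coefficients - f2$coefficients)), 1e-8)
})

test_that("exchangeable working correlation is recovered from paired eyes", {
  set.seed(43)
  n <- 400; rho <- 0.5
  u <- rnorm(n)
  y <- c(sqrt(rho) * u + sqrt(1 - rho) * rnorm(n),
         sqrt(rho) * u + sqrt(1 - rho) * rnorm(n))
  d <- data.frame(y = y, id = rep(1:n, 2))
  f <- fit_gee(y ~ 1, d, id = id)
  expect_lt(abs(f$alpha - rho), 0.1)
  expect_lt(abs(f$phi - 1), 0.15)
})

test_that("sandwich covariance is symmetric PSD and CIs bracket the estimate", {
  set.seed(44)
  d <- data.frame(y = rnorm(60), x = rnorm(60), id = rep(1:30, each = 2))
  f <- fit_gee(y ~ x, d, id = id)
  expect_equal(f$robust_cov, t(f$robust_cov))
  expect_true(all(eigen(f$robust_cov, symmetric = TRUE)$values > -1e-12))
  tab <- summary_gee_table(f)
  expect_true(all(tab$ci_low <= tab$beta & tab$beta <= tab$ci_high))
})

test_that("degenerate designs are rejected", {
  d <- data.frame(y = rnorm(10), x = 1, id = rep(1, 10))
  expect_error(fit_gee(y ~ x, d, id = id))
  d2 <- data.frame(y = rnorm(10), x = rnorm(10), id = rep(1:5, 2))
  d2$x2 <- d2$x * 2
  expect_error(fit_gee(y ~ x + x2, d2, id = id), "rank-deficient")
})

test_that("QIC penalty grows by about 2 per pure-noise covariate", {
  set.seed(45)
  diffs <- replicate(40, {
    d <- data.frame(y = rnorm(120), x = rnorm(120), id = rep(1:60, each = 2))
    d$junk <- rnorm(120)
    f0 <- fit_gee(y ~ x, d, id = id)
    f1 <- fit_gee(y ~ x + junk, d, id = id)
    pen <- function(f) f$qic - sum(f$residuals^2)
    pen(f1) - pen(f0)
  })
  expect_lt(abs(mean(diffs) - 2), 0.5)
})

test_that("QIC under exchangeable and independence agree for independent data", {
  set.seed(46)
  d <- data.frame(y = rnorm(120), x = rnorm(120), id = rep(1:60, each = 2))
  f_ex <- fit_gee(y ~ x, d, id = id)
  f_in <- fit_gee(y ~ x, d, id = id, corstr = "independence")
  expect_lt(abs(f_ex$qic - f_in$qic), 2)
})

test_that("QIC selects the correctly specified mean model", {
  set.seed(47)
  wins <- replicate(100, {
    id <- rep(1:40, each = 2)
    u <- rnorm(40)[id]
    x <- rnorm(80)
    y <- 1 + 0.8 * x + 0.7 * u + rnorm(80, sd = 0.7)
    d <- data.frame(y = y, x = x, id = id)
    f_good <- fit_gee(y ~ x, d, id = id)
    f_bad <- fit_gee(y ~ 1, d, id = id)
    f_good$qic < f_bad$qic
  })
  expect_gte(mean(wins), 0.9)
})
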
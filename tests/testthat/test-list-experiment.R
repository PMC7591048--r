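test_that("difference in means: arithmetic, identity and error cases", {
  d <- manual_list_data(c(2, 2, 2, 2), c(3, 2, 3, 2))
  est <- estimate_support_diff_means(d, 1)
  expect_equal(est$support_hat, 0.5)
  expect_equal(est$n_control, 4)
  expect_equal(est$n_treat, 4)

  d2 <- manual_list_data(c(1, 2, 3), c(1, 2, 3))
  expect_equal(estimate_support_diff_means(d2, 1)$support_hat, 0)

  expect_error(estimate_support_diff_means(d, 2), "T2")
  expect_error(estimate_support_diff_means(d, 1, scope = "ES"), "control")
  expect_error(estimate_support_diff_means(d, 3), "statement")
})

test_that("regression with no covariates reproduces difference in means exactly", {
  d <- generate_survey(small_config(seed = 41))
  for (st in 1:2) {
    dm <- estimate_support_diff_means(d, st)
    rg <- estimate_support_regression(d, st, covariates = character(0))
    expect_equal(rg$support_hat, dm$support_hat, tolerance = 1e-10)
  }
})

test_that("regression errors on a covariate collinear with treatment", {
  d <- generate_survey(small_config(seed = 42))
  d$treat_copy <- as.integer(d$arm == "T1")
  expect_error(estimate_support_regression(d, 1, covariates = "treat_copy"),
               "collinear")
})

test_that("list estimators recover true support on synthetic data", {
  cfg <- survey_config(n_per_country = c(IT = 3400L, ES = 3400L, UK = 3400L),
                       true_support = c(0.62, 0.7), seed = 43)
  d <- generate_survey(cfg)
  dm <- estimate_support_diff_means(d, 1)
  rg <- estimate_support_regression(d, 1)
  expect_lt(abs(dm$support_hat - 0.62), 3 * dm$se)
  expect_lt(abs(rg$support_hat - 0.62), 3 * rg$se)
  # randomization: adjustment should not move the estimate much
  expect_lt(abs(dm$support_hat - rg$support_hat), 0.05)
})

test_that("direct estimator: counting, boundary and lying cases", {
  d <- data.frame(country = "IT", arm = "direct",
                  direct_sens1 = c(rep(1, 7), rep(0, 3)))
  est <- estimate_direct(d, 1)
  expect_equal(est$support_hat, 0.7)
  expect_equal(est$n, 10)

  d_all <- data.frame(country = "IT", arm = "direct", direct_sens1 = rep(1, 5))
  est_all <- estimate_direct(d_all, 1)
  expect_equal(est_all$support_hat, 1)
  expect_equal(est_all$se, 0)

  expect_error(estimate_direct(d, 1, scope = "UK"), "direct")
})

test_that("SDB is the list/direct difference with combined standard error", {
  lst <- econstress:::new_list_estimate(1, "pooled", "diff_means",
                                        0.62, 0.03, 100, 100)
  dir <- structure(list(statement = 1L, scope = "pooled", support_hat = 0.56,
                        se = 0.04, n = 50), class = "direct_estimate")
  sdb <- estimate_sdb(lst, dir)
  expect_equal(sdb$sdb, 0.06)
  expect_equal(sdb$se, sqrt(0.03^2 + 0.04^2))

  dir2 <- dir; dir2$statement <- 2L
  expect_error(estimate_sdb(lst, dir2), "different statements")
})

test_that("SDB recovery: lambda * p oracle and null behaviour", {
  # lambda = 0.15, p = 0.6 -> SDB = 0.09
  cfg <- survey_config(n_per_country = c(IT = 3400L, ES = 3300L, UK = 3300L),
                       true_support = c(0.6, 0.7), liar_rate = c(0.15, 0),
                       seed = 44)
  d <- generate_survey(cfg)
  sdb <- estimate_sdb(estimate_support_diff_means(d, 1), estimate_direct(d, 1))
  expect_lt(abs(sdb$sdb - 0.09), 3 * sdb$se)

  # lambda = 0: SDB not significant in most replicates
  hits <- sapply(1:20, function(r) {
    cfg0 <- survey_config(n_per_country = c(IT = 1200L, ES = 1200L, UK = 1200L),
                          true_support = c(0.6, 0.7), liar_rate = c(0, 0),
                          seed = 100 + r)
    d0 <- generate_survey(cfg0)
    s <- estimate_sdb(estimate_support_diff_means(d0, 1),
                      estimate_direct(d0, 1))
    abs(s$t_stat) > 1.96
  })
  expect_lte(mean(hits), 0.25)
})

test_that("design-effect type proportions sum to one and behave at the interior", {
  for (seed in 1:3) {
    d <- generate_survey(small_config(seed = 50 + seed))
    res <- design_effect_test(d, 1)
    expect_equal(sum(res$pi_hat$pi), 1, tolerance = 1e-10)
    expect_true(res$p_value >= 0 && res$p_value <= 1)
  }
  # comfortably positive proportions -> corrected p saturates at 1
  cfg <- survey_config(n_per_country = c(IT = 2000L, ES = 2000L, UK = 2000L),
                       seed = 54)
  d <- generate_survey(cfg)
  res <- design_effect_test(d, 1)
  if (res$min_pi_hat > 0.01) expect_equal(res$p_value, 1)
  expect_false(res$reject)
})

test_that("design-effect test flags small arms as low power", {
  d <- manual_list_data(rep(c(0, 1, 2), 4), rep(c(1, 2, 3), 4))
  expect_warning(res <- design_effect_test(d, 1), "low-power")
  expect_true(res$low_power)
})

test_that("balance tests: randomized data, rigged covariate, constant covariate", {
  d <- generate_survey(small_config(seed = 60))
  bt <- balance_tests(d)
  expect_true(all(bt$p_value > 1e-4, na.rm = TRUE))

  d$rigged <- as.numeric(d$arm == "T1") * 10 + rnorm(nrow(d), 0, 0.1)
  d$flat <- 1
  bt2 <- balance_tests(d, covariates = c("rigged", "flat", "age"))
  expect_lt(bt2$p_value[bt2$covariate == "rigged"], 1e-10)
  expect_match(bt2$note[bt2$covariate == "flat"], "constant")
  expect_true(is.na(bt2$p_value[bt2$covariate == "flat"]))
})
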
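test_that("post-stratification weights satisfy the calibration identity", {
  d <- generate_survey(small_config(seed = 101))
  mg <- synthetic_margins()
  w <- poststratify(d, mg)
  expect_true(all(w > 0))
  for (cty in c("IT", "ES", "UK")) {
    i <- d$country == cty
    expect_equal(mean(w[i]), 1, tolerance = 1e-10)
    key <- paste(d$gender[i], age_band(d$age[i]), d$region[i])
    wshare <- tapply(w[i], key, sum) / sum(w[i])
    mgc <- mg[mg$country == cty, ]
    pshare <- setNames(mgc$count / sum(mgc$count),
                       paste(mgc$gender, mgc$age_band, mgc$region))
    expect_equal(as.numeric(wshare), as.numeric(pshare[names(wshare)]),
                 tolerance = 1e-10)
  }
})

test_that("undersampled cells get proportionally larger weights", {
  # one cell sampled at half its population share -> raw weight ratio of 2
  d <- data.frame(
    country = "IT",
    gender = rep(c("F", "M"), c(100, 300)),
    age = 25,
    region = "North"
  )
  mg <- data.frame(country = "IT",
                   gender = c("F", "M"), age_band = "18-35", region = "North",
                   count = c(200, 200))
  w <- poststratify(d, mg)
  # F sampled at 25% vs 50% population share; M at 75% vs 50%
  expect_equal(unique(w[d$gender == "F"]) / unique(w[d$gender == "M"]),
               (0.5 / 0.25) / (0.5 / 0.75), tolerance = 1e-10)
})

test_that("empty cells collapse the region dimension before failing", {
  d <- generate_survey(small_config(seed = 102))
  d_it <- d[d$country == "IT", ]
  d_it <- d_it[d_it$region != "Isles", ]   # no one sampled in one region
  mg <- synthetic_margins()
  expect_silent(w <- poststratify(d_it, mg[mg$country == "IT", ]))
  expect_match(attr(w, "collapsed"), "gender x age_band")
  expect_equal(mean(w), 1, tolerance = 1e-10)
})

test_that("high-risk classification uses an inclusive threshold", {
  pred <- c(0.4999, 0.5, 0.7, 0.25, 1)
  expect_equal(classify_high_risk(pred), c(0L, 1L, 1L, 0L, 1L))
  expect_equal(classify_high_risk(pred, threshold = 1.01), rep(0L, 5))
  expect_equal(classify_high_risk(pred, threshold = 0.25), rep(1L, 5))
})

test_that("projection: boundary cases, pooling arithmetic and weight rescaling", {
  ind <- rep(1, 6)
  w <- runif(6, 0.5, 2)
  cty <- rep(c("IT", "ES", "UK"), each = 2)
  expect_equal(unname(project_high_risk_share(ind, w, cty)), rep(1, 4))

  # equal weights -> unweighted mean; equal populations -> simple average
  ind2 <- c(1, 0, 1, 1, 0, 1)
  pops <- c(IT = 1e6, ES = 1e6, UK = 1e6)
  sh <- project_high_risk_share(ind2, rep(1, 6), cty, pops)
  expect_equal(unname(sh[c("IT", "ES", "UK")]), c(0.5, 1, 0.5))
  expect_equal(unname(sh["pooled"]), mean(c(0.5, 1, 0.5)))

  # rescaling all weights leaves every share unchanged
  w2 <- runif(6)
  expect_equal(project_high_risk_share(ind2, w2, cty, pops),
               project_high_risk_share(ind2, 7.3 * w2, cty, pops),
               tolerance = 1e-12)
  expect_error(project_high_risk_share(ind2, w2[-1], cty), "equal length")
})

test_that("pooled share is the population-weighted mean of country shares", {
  shares <- c(0.4, 0.5, 0.4)
  ind <- c(rep(c(1, 0), c(4, 6)), rep(c(1, 0), c(5, 5)), rep(c(1, 0), c(4, 6)))
  cty <- rep(c("IT", "ES", "UK"), each = 10)
  out <- project_high_risk_share(ind, rep(1, 30), cty,
                                 c(IT = 2e6, ES = 2e6, UK = 2e6))
  expect_equal(unname(out["pooled"]), mean(shares), tolerance = 1e-12)
})

test_that("risk forest recovers a strong signal and refuses tiny samples", {
  cfg <- survey_config(n_per_country = c(IT = 700L, ES = 700L, UK = 700L),
                       vulnerability_loading = 1.2, noise_sd = 0.4, seed = 103)
  d <- generate_survey(cfg)
  idx <- score_stress_index(d)
  m <- fit_risk_model(d, idx, n_trees = 150, seed = 1)
  expect_gt(m$fit_rank_cor, 0.6)
  expect_true(all(m$predictions >= 0.25 & m$predictions <= 1))
  expect_length(m$oob_mse, 150)

  expect_error(fit_risk_model(d[1:50, ], idx[1:50]), "100")
})

test_that("with no signal the forest has no out-of-bag explanatory power", {
  cfg <- survey_config(n_per_country = c(IT = 500L, ES = 500L, UK = 500L),
                       vulnerability_loading = 0, seed = 104)
  d <- generate_survey(cfg)
  idx <- score_stress_index(d)
  m <- fit_risk_model(d, idx, n_trees = 100, seed = 2)
  oob_r2 <- 1 - m$oob_mse[length(m$oob_mse)] / var(idx)
  expect_lt(abs(oob_r2), 0.1)
})

test_that("forest fits are reproducible given a seed", {
  d <- generate_survey(small_config(seed = 105))
  idx <- score_stress_index(d)
  m1 <- fit_risk_model(d, idx, n_trees = 60, seed = 9)
  m2 <- fit_risk_model(d, idx, n_trees = 60, seed = 9)
  expect_identical(m1$predictions, m2$predictions)
  expect_identical(m1$oob_mse, m2$oob_mse)
})

test_that("out-of-sample predictions track the full-sample model", {
  cfg <- survey_config(n_per_country = c(IT = 700L, ES = 700L, UK = 700L),
                       vulnerability_loading = 1.2, noise_sd = 0.4, seed = 106)
  d <- generate_survey(cfg)
  idx <- score_stress_index(d)
  st <- holdout_stability(d, idx, learn_fractions = c(0.25, 0.5),
                          n_trees = 120, seed = 3)
  expect_equal(st$fraction, c(0.25, 0.5))
  expect_true(all(st$rank_correlation > 0.8))
  expect_equal(st$n_train + st$n_test, rep(sum(cfg$n_per_country), 2))
})
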
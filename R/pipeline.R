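#' Run the full two-part analysis on a synthetic survey
#'
#' Convenience driver that chains every stage: generate the survey, estimate
#' support for both sensitive statements (difference in means and
#' covariate-adjusted regression, pooled and per country), quantify
#' social-desirability bias against the direct arm, run the design-effect and
#' balance diagnostics, score the stress index and its reliability, fit the
#' risk forest, post-stratify and project the high-risk share, build the
#' three PCA exposure scores, and compare distributions by first-order
#' stochastic dominance.
#'
#' Deterministic given `config$seed` (the forest seed is derived from it).
#'
#' @param config A [survey_config()].
#' @param margins Optional margins table; defaults to [synthetic_margins()].
#' @param n_trees Trees for the risk forest.
#' @param population_totals Country population totals used for the pooled
#'   projection (must match the margins totals).
#' @return A list with components `data`, `support` (data frame of list and
#'   direct estimates and SDB across statements and scopes), `design_effect`,
#'   `balance`, `alpha`, `index`, `risk_model`, `weights`, `high_risk_shares`,
#'   `exposure` (per-dimension `exposure_score`s), `dominance`.
#' @export
run_full_pipeline <- function(config = survey_config(),
                              margins = NULL,
                              n_trees = 550L,
                              population_totals = c(IT = 44.3e6, ES = 34.7e6,
                                                    UK = 48.9e6)) {
  data <- generate_survey(config)
  if (is.null(margins)) margins <- synthetic_margins(population_totals)

  scopes <- c("pooled", "IT", "ES", "UK")
  support <- do.call(rbind, lapply(1:2, function(st) {
    do.call(rbind, lapply(scopes, function(sc) {
      dm <- estimate_support_diff_means(data, st, sc)
      rg <- estimate_support_regression(data, st, sc)
      dir <- estimate_direct(data, st, sc)
      sdb <- estimate_sdb(rg, dir)
      data.frame(statement = st, scope = sc,
                 list_diff_means = dm$support_hat, se_diff_means = dm$se,
                 list_regression = rg$support_hat, se_regression = rg$se,
                 direct = dir$support_hat, se_direct = dir$se,
                 sdb = sdb$sdb, se_sdb = sdb$se, t_sdb = sdb$t_stat)
    }))
  }))

  design_effect <- lapply(1:2, function(st) design_effect_test(data, st))
  balance <- balance_tests(data)

  index <- score_stress_index(data)
  alpha <- cronbach_alpha(data[paste0("mh", 1:8)])

  model <- fit_risk_model(data, index, n_trees = n_trees,
                          seed = config$seed + 104729L)
  high <- classify_high_risk(model)
  rows <- model$train_rows
  weights <- poststratify(data[rows, , drop = FALSE], margins)
  shares <- project_high_risk_share(high, weights, data$country[rows],
                                    population_totals)

  exposure <- lapply(
    stats::setNames(nm = c("susceptibility", "vulnerability", "behaviour")),
    function(dim) pca_exposure_score(exposure_items(data, dim), dim))

  dominance <- dominance_table(model$predictions,
                               lapply(exposure, `[[`, "score"))

  list(data = data, support = support, design_effect = design_effect,
       balance = balance, alpha = alpha, index = index, risk_model = model,
       weights = weights, high_risk_shares = shares, exposure = exposure,
       dominance = dominance)
}
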
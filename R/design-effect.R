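#' Design-effect diagnostic for a list experiment
#'
#' The identifying assumption of the item-count technique is that adding the
#' sensitive statement does not change answers to the control statements. Its
#' violation shows up as negative estimated proportions of respondent types.
#' With J = 4 control items, let `G(y)` and `H(y)` be the empirical CDFs of
#' the item count in the control and treatment arm. The estimated proportion
#' of respondents with control-item subtotal y who agree (z = 1) or disagree
#' (z = 0) with the sensitive item is
#'
#'   pi(y, 1) = G(y) - H(y),    pi(y, 0) = H(y) - G(y - 1),   y = 0..J,
#'
#' with `G(-1) = 0`. These sum to 1 by construction. The boundary entries
#' `pi(J, 1) = 1 - H(J)` and `pi(0, 0) = H(0)` are nonnegative by
#' construction, so only the remaining `2(J + 1) - 2` proportions are tested:
#' each gets a one-sided normal test of H0: pi >= 0 against pi < 0, and the
#' smallest p-value is Bonferroni-corrected over the tested family.
#'
#' @param data A survey dataset.
#' @param statement 1 or 2.
#' @param scope `"pooled"` or a country code.
#' @param alpha Significance level for the rejection decision.
#' @return A `design_effect_result`: `pi_hat` (data frame of type
#'   proportions), `min_pi_hat`, `p_value` (Bonferroni-corrected), `reject`,
#'   `low_power` flag.
#' @export
design_effect_test <- function(data, statement, scope = "pooled",
                               alpha = 0.05) {
  statement <- check_statement(statement)
  d <- filter_scope(data, scope)
  treat_arm <- c("T1", "T2")[statement]
  y_c <- d$item_count[d$arm == "control"]
  y_t <- d$item_count[d$arm == treat_arm]
  if (length(y_c) == 0 || length(y_t) == 0)
    stop("control and treatment arms must both be nonempty", call. = FALSE)
  low_power <- length(y_c) < 30 || length(y_t) < 30
  if (low_power)
    warning("fewer than 30 respondents in an arm; design-effect test is low-powered")

  J <- 4L
  G <- function(y) if (y < 0) 0 else mean(y_c <= y)
  H <- function(y) mean(y_t <= y)
  n_c <- length(y_c)
  n_t <- length(y_t)

  ys <- 0:J
  pi1 <- vapply(ys, function(y) G(y) - H(y), numeric(1))          # z = 1
  pi0 <- vapply(ys, function(y) H(y) - G(y - 1), numeric(1))      # z = 0
  pi_hat <- data.frame(y = rep(ys, 2L), z = rep(c(1L, 0L), each = J + 1L),
                       pi = c(pi1, pi0))

  # Variance of an empirical CDF difference across independent arms.
  var_diff <- function(g, h) g * (1 - g) / n_c + h * (1 - h) / n_t

  test_one <- function(y, z) {
    if (z == 1L) {
      est <- G(y) - H(y); v <- var_diff(G(y), H(y))
    } else {
      est <- H(y) - G(y - 1); v <- var_diff(G(y - 1), H(y))
    }
    if (v <= 0) return(if (est < 0) 0 else 1)
    stats::pnorm(est / sqrt(v))   # one-sided: small when pi_hat is negative
  }

  testable <- rbind(data.frame(y = 0:(J - 1L), z = 1L),
                    data.frame(y = 1:J, z = 0L))
  pvals <- mapply(test_one, testable$y, testable$z)
  p_corr <- min(1, nrow(testable) * min(pvals))

  structure(list(statement = statement, scope = scope,
                 pi_hat = pi_hat,
                 min_pi_hat = min(pi_hat$pi),
                 p_value = p_corr,
                 reject = p_corr < alpha,
                 low_power = low_power,
                 n_control = n_c, n_treat = n_t),
            class = "design_effect_result")
}

#' Covariate balance tests across the four randomized arms
#'
#' For each covariate, a joint equality test across the four arms: one-way
#' ANOVA F for numeric covariates, a chi-squared contingency test for
#' categorical ones. Under successful randomization roughly 5% of covariates
#' reject at the 5% level.
#'
#' @param data A survey dataset.
#' @param covariates Covariate column names; sensible default spanning the
#'   demographic and socio-economic blocks.
#' @param categorical Names within `covariates` to treat as categorical.
#' @return Data frame with columns `covariate`, `test`, `statistic`,
#'   `p_value`, `note` (constant covariates are skipped with a note).
#' @export
balance_tests <- function(data,
                          covariates = c("gender", "age", "married",
                                         "unemployed", "household_size",
                                         "children_school", "income_category",
                                         "education", "homeowner",
                                         "living_area", "buffer_stock",
                                         "stress_events", "income_loss"),
                          categorical = c("gender", "married", "unemployed",
                                          "homeowner", "income_loss")) {
  arm <- factor(data$arm)
  rows <- lapply(covariates, function(v) {
    x <- data[[v]]
    if (is.null(x))
      return(data.frame(covariate = v, test = NA_character_,
                        statistic = NA_real_, p_value = NA_real_,
                        note = "column not found"))
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2)
      return(data.frame(covariate = v, test = NA_character_,
                        statistic = NA_real_, p_value = NA_real_,
                        note = "constant; skipped"))
    if (v %in% categorical || is.character(x) || is.factor(x)) {
      tst <- suppressWarnings(stats::chisq.test(table(x[ok], arm[ok])))
      data.frame(covariate = v, test = "chisq",
                 statistic = unname(tst$statistic),
                 p_value = tst$p.value, note = "")
    } else {
      fit <- stats::aov(x[ok] ~ arm[ok])
      tab <- summary(fit)[[1]]
      data.frame(covariate = v, test = "anova",
                 statistic = tab[["F value"]][1],
                 p_value = tab[["Pr(>F)"]][1], note = "")
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.design_effect_result <- function(x, ...) {
  cat(sprintf("Design-effect test, statement %d, scope %s\n",
              x$statement, x$scope))
  cat(sprintf("  min pi_hat = %.4f, Bonferroni p = %.4f, reject = %s\n",
              x$min_pi_hat, x$p_value, x$reject))
  invisible(x)
}
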
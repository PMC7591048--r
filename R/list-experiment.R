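#' List-experiment support estimate: difference in means
#'
#' Estimates the population share agreeing with a sensitive statement as the
#' difference between the mean item count in the statement's treatment arm
#' (shown 4 control items + the sensitive item) and in the control arm (shown
#' the 4 control items only). The standard error uses the Welch two-sample
#' formula.
#'
#' @param data A survey dataset from [generate_survey()] or read from file.
#' @param statement 1 or 2, selecting treatment arm T1 or T2.
#' @param scope `"pooled"` or a country code.
#' @return A `list_estimate`: statement, scope, method, `support_hat`, `se`,
#'   `t_stat`, `n_control`, `n_treat`.
#' @export
estimate_support_diff_means <- function(data, statement, scope = "pooled") {
  statement <- check_statement(statement)
  d <- filter_scope(data, scope)
  treat_arm <- c("T1", "T2")[statement]
  y_c <- d$item_count[d$arm == "control"]
  y_t <- d$item_count[d$arm == treat_arm]
  if (length(y_c) == 0)
    stop(sprintf("no control-arm respondents in scope %s", scope), call. = FALSE)
  if (length(y_t) == 0)
    stop(sprintf("no %s-arm respondents in scope %s", treat_arm, scope),
         call. = FALSE)
  est <- mean(y_t) - mean(y_c)
  se <- sqrt(stats::var(y_t) / length(y_t) + stats::var(y_c) / length(y_c))
  new_list_estimate(statement, scope, "diff_means", est, se,
                    n_control = length(y_c), n_treat = length(y_t))
}

#' List-experiment support estimate: linear regression
#'
#' Regresses the item count on a treatment indicator plus covariates over the
#' control and treatment subsample; the treatment coefficient estimates the
#' agreeing share. Standard errors are heteroskedasticity-robust (HC1).
#' Covariates are not of substantive interest here; they only absorb residual
#' variance under randomization.
#'
#' @inheritParams estimate_support_diff_means
#' @param covariates Character vector of covariate column names;
#'   `default_covariates(scope)` mirrors the standard adjustment set (female
#'   dummy, age, marital status, unemployment, household size, children of
#'   school age, country dummies when pooled, income level, education,
#'   homeownership, living area). An empty vector reproduces the
#'   difference-in-means estimate exactly.
#' @return A `list_estimate` with `method = "regression"`.
#' @export
estimate_support_regression <- function(data, statement, scope = "pooled",
                                        covariates = default_covariates(scope)) {
  statement <- check_statement(statement)
  d <- filter_scope(data, scope)
  treat_arm <- c("T1", "T2")[statement]
  d <- d[d$arm %in% c("control", treat_arm), , drop = FALSE]
  if (!any(d$arm == "control") || !any(d$arm == treat_arm))
    stop("control or treatment arm empty within scope", call. = FALSE)

  d$treat <- as.integer(d$arm == treat_arm)
  vars <- c("item_count", "treat", covariates)
  missing_cols <- setdiff(vars, names(d))
  if (length(missing_cols))
    stop("covariates not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  cc <- stats::complete.cases(d[vars])
  n_dropped <- sum(!cc)
  d <- d[cc, , drop = FALSE]

  fml <- stats::reformulate(c("treat", covariates), response = "item_count")
  fit <- stats::lm(fml, data = d)
  aliased <- names(which(is.na(stats::coef(fit))))
  if (length(aliased))
    stop("rank-deficient design matrix; collinear columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)

  est <- unname(stats::coef(fit)["treat"])
  se <- sqrt(sandwich::vcovHC(fit, type = "HC1")["treat", "treat"])
  out <- new_list_estimate(statement, scope, "regression", est, se,
                           n_control = sum(d$treat == 0),
                           n_treat = sum(d$treat == 1))
  out$n_dropped_missing <- n_dropped
  out$fit <- fit
  out
}

#' Direct-questioning support estimate
#'
#' Share of direct-arm respondents who selected the sensitive statement when
#' shown all six statements individually. Respondents who did not select the
#' statement count as disagreeing. Binomial standard error.
#'
#' @inheritParams estimate_support_diff_means
#' @return List with `statement`, `scope`, `support_hat`, `se`, `n`.
#' @export
estimate_direct <- function(data, statement, scope = "pooled") {
  statement <- check_statement(statement)
  d <- filter_scope(data, scope)
  ans <- d[[paste0("direct_sens", statement)]][d$arm == "direct"]
  ans <- ans[!is.na(ans)]
  if (length(ans) == 0)
    stop(sprintf("no direct-arm respondents in scope %s", scope), call. = FALSE)
  p <- mean(ans)
  structure(list(statement = statement, scope = scope,
                 support_hat = p,
                 se = sqrt(p * (1 - p) / length(ans)),
                 n = length(ans)),
            class = "direct_estimate")
}

#' Social-desirability bias estimate
#'
#' Contrast of the list-experiment support estimate with the direct-question
#' share: `sdb = list - direct`. A positive SDB means respondents under-report
#' agreement when asked directly. The two estimates come from disjoint random
#' subsamples, so their variances add.
#'
#' @param list_est A `list_estimate`.
#' @param direct_est A direct estimate from [estimate_direct()] for the same
#'   statement and scope.
#' @return An `sdb_estimate`: statement, scope, `list_support`,
#'   `direct_support`, `sdb`, `se`, `t_stat`.
#' @export
estimate_sdb <- function(list_est, direct_est) {
  if (list_est$statement != direct_est$statement ||
      list_est$scope != direct_est$scope)
    stop("list and direct estimates refer to different statements or scopes",
         call. = FALSE)
  sdb <- list_est$support_hat - direct_est$support_hat
  se <- sqrt(list_est$se^2 + direct_est$se^2)
  structure(list(statement = list_est$statement, scope = list_est$scope,
                 list_support = list_est$support_hat,
                 direct_support = direct_est$support_hat,
                 sdb = sdb, se = se,
                 t_stat = if (se > 0) sdb / se else NA_real_),
            class = "sdb_estimate")
}

new_list_estimate <- function(statement, scope, method, est, se,
                              n_control, n_treat) {
  structure(list(statement = statement, scope = scope, method = method,
                 support_hat = est, se = se,
                 t_stat = if (se > 0) est / se else NA_real_,
                 n_control = n_control, n_treat = n_treat),
            class = "list_estimate")
}

check_statement <- function(statement) {
  if (!(length(statement) == 1 && statement %in% c(1, 2)))
    stop("statement must be 1 or 2", call. = FALSE)
  as.integer(statement)
}

#' Default regression adjustment set
#'
#' @param scope Analysis scope; country dummies are included only when pooled.
#' @return Character vector of covariate column names.
#' @export
default_covariates <- function(scope = "pooled") {
  covs <- c("gender", "age", "married", "unemployed", "household_size",
            "children_school", "income_category", "education", "homeowner",
            "living_area")
  if (identical(scope, "pooled")) covs <- c(covs, "country")
  covs
}

#' @export
print.list_estimate <- function(x, ...) {
  cat(sprintf(
    "List-experiment estimate (%s), statement %d, scope %s\n", x$method,
    x$statement, x$scope))
  cat(sprintf("  support = %.4f (se %.4f, t %.2f), n_control %d, n_treat %d\n",
              x$support_hat, x$se, x$t_stat, x$n_control, x$n_treat))
  invisible(x)
}

#' @export
print.sdb_estimate <- function(x, ...) {
  cat(sprintf("SDB, statement %d, scope %s\n", x$statement, x$scope))
  cat(sprintf("  list %.4f - direct %.4f = %.4f (se %.4f, t %.2f)\n",
              x$list_support, x$direct_support, x$sdb, x$se, x$t_stat))
  invisible(x)
}
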
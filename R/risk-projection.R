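#' Names of the nine economic-vulnerability predictors
#'
#' Household income, unemployment, homeownership, living space, household
#' size, children of school age, financial buffer stock, negative events in
#' the previous week, and income/earnings loss.
#'
#' @return Character vector of column names.
#' @export
risk_predictors <- function() {
  c("income_category", "unemployed", "homeowner", "living_area",
    "household_size", "children_school", "buffer_stock", "stress_events",
    "income_loss")
}

#' Fit the stress-risk random forest
#'
#' Regression random forest (bagged trees, 550 by default) of the stress
#' index on the nine economic predictors. Ordinal predictors enter as
#' integers. Records the out-of-bag MSE curve by tree count, variable
#' importance, and the in-sample Spearman fit correlation. Fitted values are
#' clipped to the \[0.25, 1\] range of the outcome.
#'
#' @param data A survey dataset containing the predictor columns.
#' @param index Stress-index outcome aligned with `data` rows (from
#'   [score_stress_index()]).
#' @param predictors Predictor column names.
#' @param n_trees Number of trees (default 550).
#' @param mtry Candidate variables per split; default one third of the
#'   predictors.
#' @param seed Optional seed set immediately before fitting.
#' @return A `risk_model`: the `forest`, in-sample `predictions` (aligned
#'   with the complete-case training rows; `train_rows` gives their row
#'   indices in `data`), `oob_mse` curve, `importance`, `fit_rank_cor`.
#' @export
fit_risk_model <- function(data, index, predictors = risk_predictors(),
                           n_trees = 550L,
                           mtry = max(1L, floor(length(predictors) / 3)),
                           seed = NULL) {
  stopifnot(length(index) == nrow(data))
  missing_cols <- setdiff(predictors, names(data))
  if (length(missing_cols))
    stop("missing predictor columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  X <- data[predictors]
  keep <- stats::complete.cases(X) & !is.na(index)
  if (sum(keep) < 100)
    stop("fewer than 100 complete training rows; refusing to fit",
         call. = FALSE)
  X <- X[keep, , drop = FALSE]
  y <- index[keep]
  if (!is.null(seed)) set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = y, ntree = n_trees, mtry = mtry,
                                   importance = TRUE)
  pred <- clip_index(stats::predict(rf, newdata = X))
  structure(list(forest = rf,
                 predictors = predictors,
                 train_rows = which(keep),
                 predictions = pred,
                 oob_mse = rf$mse,
                 importance = rf$importance,
                 fit_rank_cor = stats::cor(pred, y, method = "spearman")),
            class = "risk_model")
}

clip_index <- function(x) pmin(1, pmax(0.25, x))

#' Classify respondents as high mental-health risk
#'
#' High risk means a predicted stress index at or above the threshold
#' (inclusive; a prediction of exactly 0.5 counts as high risk).
#'
#' @param model A `risk_model`, or a numeric vector of predictions.
#' @param newdata Optional data to predict on; defaults to the model's
#'   in-sample predictions.
#' @param threshold Classification threshold on the 0.25-1 index scale.
#' @return Integer 0/1 vector.
#' @export
classify_high_risk <- function(model, newdata = NULL, threshold = 0.5) {
  pred <- if (is.numeric(model)) {
    model
  } else if (is.null(newdata)) {
    model$predictions
  } else {
    clip_index(stats::predict(model$forest,
                              newdata = newdata[model$predictors]))
  }
  as.integer(pred >= threshold)
}

#' Out-of-sample stability of the risk predictions
#'
#' For each learning fraction, refits the forest on a random subsample and
#' predicts the held-out remainder; reports the Spearman correlation between
#' those out-of-sample predictions and the full-sample model's predictions on
#' the same respondents. High correlations indicate the in-sample
#' classification is not an artifact of overfitting.
#'
#' @param data A survey dataset.
#' @param index Stress-index outcome aligned with `data`.
#' @param learn_fractions Fractions of the sample used for learning.
#' @param n_trees Trees per forest.
#' @param seed Seed controlling both the full fit and the subsampling.
#' @param predictors Predictor columns.
#' @return Data frame: `fraction`, `n_train`, `n_test`, `rank_correlation`.
#' @export
holdout_stability <- function(data, index,
                              learn_fractions = c(0.15, 0.25, 0.33, 0.50),
                              n_trees = 550L, seed = 1L,
                              predictors = risk_predictors()) {
  full <- fit_risk_model(data, index, predictors, n_trees = n_trees,
                         seed = seed)
  rows <- full$train_rows
  d <- data[rows, , drop = FALSE]
  y <- index[rows]
  full_pred <- full$predictions
  out <- lapply(learn_fractions, function(f) {
    set.seed(seed + round(1000 * f))
    n <- nrow(d)
    tr <- sample.int(n, max(2, round(f * n)))
    sub <- fit_risk_model(d[tr, , drop = FALSE], y[tr], predictors,
                          n_trees = n_trees)
    te <- setdiff(seq_len(n), tr)
    pred_oos <- clip_index(stats::predict(sub$forest,
                                          newdata = d[te, predictors,
                                                      drop = FALSE]))
    data.frame(fraction = f, n_train = length(tr), n_test = length(te),
               rank_correlation = stats::cor(pred_oos, full_pred[te],
                                             method = "spearman"))
  })
  do.call(rbind, out)
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("Stress-risk random forest: %d trees, %d predictors, n = %d\n",
              length(x$oob_mse), length(x$predictors), length(x$predictions)))
  cat(sprintf("  final OOB MSE %.4f; in-sample Spearman fit %.4f\n",
              x$oob_mse[length(x$oob_mse)], x$fit_rank_cor))
  invisible(x)
}
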
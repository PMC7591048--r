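#' Score the eight-item stress/anxiety/depression index
#'
#' The instrument is an eight-item adaptation of the DASS-21 and SASRQ
#' scales, each item answered on a 1-4 Likert scale (1 = "rarely or none of
#' the time (less than one day)" ... 4 = "most or all of the time (5-7
#' days)"). The index is the item mean divided by 4, so it lives on
#' \[0.25, 1\]: 0.25 iff all items are 1, 1 iff all items are 4.
#'
#' Respondents with up to two missing items get a prorated mean over the
#' non-missing items; respondents with fewer than `min_items` answered items
#' are excluded (index `NA`), with their ids recorded in the `"excluded_ids"`
#' attribute.
#'
#' @param data A survey dataset (columns `mh1..mh8`) or a numeric
#'   matrix/data.frame of eight item columns.
#' @param min_items Minimum answered items required to score a respondent.
#' @return Numeric vector of index values in \[0.25, 1\] (NA for excluded
#'   respondents), with attributes `n_items_used` and `excluded_ids`.
#' @export
score_stress_index <- function(data, min_items = 6L) {
  items <- mh_item_matrix(data)
  rng <- range(items, na.rm = TRUE)
  if (rng[1] < 1 || rng[2] > 4)
    stop("mental-health items must lie in {1, 2, 3, 4}", call. = FALSE)
  n_used <- rowSums(!is.na(items))
  idx <- rowMeans(items, na.rm = TRUE) / 4
  excluded <- n_used < min_items
  idx[excluded] <- NA_real_
  ids <- if (is.data.frame(data) && !is.null(data$id)) data$id
         else seq_len(nrow(items))
  attr(idx, "n_items_used") <- n_used
  attr(idx, "excluded_ids") <- ids[excluded]
  idx
}

mh_item_matrix <- function(data) {
  cols <- paste0("mh", 1:8)
  if (is.data.frame(data) && all(cols %in% names(data))) {
    as.matrix(data[cols])
  } else {
    m <- as.matrix(data)
    if (ncol(m) != 8)
      stop("expected the eight mh1..mh8 item columns", call. = FALSE)
    m
  }
}

#' Symptom prevalence table
#'
#' Per item and per country (plus the pooled total), the share of respondents
#' reporting the symptom at least "some or a little of the time (1-2 days)",
#' i.e. an item response at or above `threshold`.
#'
#' @param data A survey dataset.
#' @param threshold Likert level counted as symptomatic (default 2).
#' @return Data frame: one row per item, columns `item`, one per country,
#'   `Total`; entries are shares in \[0, 1\].
#' @export
prevalence_table <- function(data, threshold = 2) {
  items <- mh_item_matrix(data)
  scopes <- c(as.list(sort(unique(data$country))), list(NULL))
  names(scopes) <- c(sort(unique(data$country)), "Total")
  out <- data.frame(item = paste0("mh", 1:8))
  for (nm in names(scopes)) {
    keep <- if (is.null(scopes[[nm]])) rep(TRUE, nrow(items)) else
      data$country == scopes[[nm]]
    out[[nm]] <- colMeans(items[keep, , drop = FALSE] >= threshold,
                          na.rm = TRUE)
  }
  out
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a multi-item scale:
#' `alpha = J/(J-1) * (1 - sum_j var(item_j) / var(sum_j item_j))`.
#'
#' @param items Numeric matrix or data frame, one column per item; rows with
#'   any missing item are dropped.
#' @return Scalar alpha (at most 1; can be negative for incoherent scales).
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  J <- ncol(m)
  if (J < 2) stop("need at least two items", call. = FALSE)
  if (nrow(m) < 2) stop("need at least two complete respondents", call. = FALSE)
  total_var <- stats::var(rowSums(m))
  if (total_var == 0)
    stop("total score has zero variance; alpha undefined", call. = FALSE)
  (J / (J - 1)) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Spearman correlations of the stress index with predictors
#'
#' Rank correlations (average ranks for ties) of the scored index with each
#' predictor, with two-sided p-values from the t approximation. Spearman
#' rather than Pearson captures monotone non-linearity and is robust to
#' atypical values and response error in ordinal scales.
#'
#' @param index Numeric vector of stress-index values.
#' @param predictors Data frame of predictor columns aligned with `index`.
#' @return Data frame: `predictor`, `rho`, `p_value`, `n`, `note` (constant
#'   predictors are skipped with a note).
#' @export
spearman_correlates <- function(index, predictors) {
  stopifnot(nrow(predictors) == length(index))
  rows <- lapply(names(predictors), function(v) {
    x <- as.numeric(predictors[[v]])
    ok <- !is.na(x) & !is.na(index)
    if (length(unique(x[ok])) < 2)
      return(data.frame(predictor = v, rho = NA_real_, p_value = NA_real_,
                        n = sum(ok), note = "constant; skipped"))
    tst <- suppressWarnings(
      stats::cor.test(index[ok], x[ok], method = "spearman", exact = FALSE))
    data.frame(predictor = v, rho = unname(tst$estimate),
               p_value = tst$p.value, n = sum(ok), note = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
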
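#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Compares raw correlations with anti-image partial correlations: with
#' `R` the item correlation matrix and `Q` the matrix of partial correlations
#' obtained from `R^{-1}` (`q_ij = -R^{-1}_ij / sqrt(R^{-1}_ii R^{-1}_jj)`),
#'
#'   KMO = sum_{i != j} r_ij^2 / (sum_{i != j} r_ij^2 + sum_{i != j} q_ij^2).
#'
#' Values near 1 indicate the correlation structure is dominated by common
#' factors and is suitable for PCA/factor summarization.
#'
#' @param items Numeric matrix or data frame (>= 3 columns); rows with
#'   missing values are dropped.
#' @return Scalar KMO statistic in \[0, 1\].
#' @export
kmo_statistic <- function(items) {
  m <- as.matrix(items)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (ncol(m) < 3) stop("KMO needs at least three variables", call. = FALSE)
  R <- stats::cor(m)
  Ri <- tryCatch(solve(R), error = function(e)
    stop("correlation matrix is singular; remove redundant variables",
         call. = FALSE))
  d <- 1 / sqrt(diag(Ri))
  Q <- -Ri * outer(d, d)          # partial correlations (off-diagonal)
  off <- upper.tri(R) | lower.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
}

#' First-principal-component exposure score
#'
#' Summarizes one block of COVID-exposure items into a single score:
#' eigendecomposition of the item correlation matrix, retention by the
#' eigenvalue-greater-than-one rule, score = first-eigenvector combination of
#' the standardized items, with the sign oriented so the loading on a
#' designated anchor item is positive (so the score increases with exposure),
#' then min-max rescaled to \[0.25, 1\] to be comparable with the stress
#' index.
#'
#' @param items Numeric matrix or data frame of the block's items; rows with
#'   missing values are dropped.
#' @param dimension Label: `"susceptibility"`, `"vulnerability"` or
#'   `"behaviour"` (free-form labels allowed).
#' @param anchor Column (index or name) whose first-component loading is
#'   forced positive.
#' @return An `exposure_score`: `dimension`, `score` (per retained row, in
#'   \[0.25, 1\]), `kmo`, `eigenvalues` (descending, summing to the number of
#'   items), `n_retained` (components with eigenvalue > 1),
#'   `variance_explained` of component 1, `loadings` of component 1,
#'   `weak_first_component` flag when the first eigenvalue is <= 1.
#' @export
pca_exposure_score <- function(items, dimension = "exposure", anchor = 1L) {
  m <- as.matrix(items)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  p <- ncol(m)
  if (p < 2) stop("need at least two items", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("constant item(s): ", paste(colnames(m)[sds == 0], collapse = ", "),
         call. = FALSE)
  z <- scale(m)
  R <- stats::cor(m)
  eig <- eigen(R, symmetric = TRUE)
  v1 <- eig$vectors[, 1]
  if (is.character(anchor)) anchor <- match(anchor, colnames(m))
  if (is.na(anchor) || anchor < 1 || anchor > p)
    stop("anchor does not match an item column", call. = FALSE)
  if (v1[anchor] < 0) v1 <- -v1

  weak <- eig$values[1] <= 1
  if (weak)
    warning("first eigenvalue <= 1; no component passes the retention rule, ",
            "score built from component 1 anyway")

  raw <- drop(z %*% v1)
  rng <- range(raw)
  score <- if (rng[2] > rng[1])
    0.25 + 0.75 * (raw - rng[1]) / (rng[2] - rng[1])
  else rep(0.25, length(raw))

  # KMO is undefined for singular or < 3-variable blocks; report NA there.
  kmo <- tryCatch(kmo_statistic(m), error = function(e) NA_real_)

  structure(list(dimension = dimension,
                 score = score,
                 kmo = kmo,
                 eigenvalues = eig$values,
                 n_retained = sum(eig$values > 1),
                 variance_explained = eig$values[1] / p,
                 loadings = stats::setNames(v1, colnames(m)),
                 weak_first_component = weak),
            class = "exposure_score")
}

#' Extract an exposure item block from a survey dataset
#'
#' Susceptibility: age, the five comorbidity flags (diabetes, hypertension,
#' asthma, cardiovascular disease, cancer) and self-rated poor health.
#' Vulnerability: the quarantine-compliance obstacle items. Behaviour:
#' contacted a doctor, contacted health authorities, sought testing.
#'
#' @param data A survey dataset.
#' @param dimension One of `"susceptibility"`, `"vulnerability"`,
#'   `"behaviour"`.
#' @return Numeric matrix of the block's items.
#' @export
exposure_items <- function(data, dimension) {
  dimension <- match.arg(dimension,
                         c("susceptibility", "vulnerability", "behaviour"))
  cols <- switch(dimension,
    susceptibility = c("age", "comorb_diabetes", "comorb_hypertension",
                       "comorb_asthma", "comorb_cardio", "comorb_cancer",
                       "health_selfrated"),
    vulnerability = paste0("vuln", 1:4),
    behaviour = c("contacted_doctor", "contacted_authorities", "sought_test"))
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("missing exposure columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  as.matrix(data[cols])
}

#' @export
print.exposure_score <- function(x, ...) {
  cat(sprintf("Exposure score: %s\n", x$dimension))
  cat(sprintf("  KMO %.3f; eigenvalue 1 = %.3f (%.0f%% variance); %d component(s) retained\n",
              x$kmo, x$eigenvalues[1], 100 * x$variance_explained,
              x$n_retained))
  invisible(x)
}
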
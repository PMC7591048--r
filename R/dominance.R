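#' Empirical CDF of an index
#'
#' Thin validated wrapper around [stats::ecdf()]: `F(x)` is the share of
#' respondents whose index is at most `x`, a right-continuous nondecreasing
#' step function from 0 to 1.
#'
#' @param values Nonempty numeric vector.
#' @return A function of class `ecdf`.
#' @export
index_ecdf <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no non-missing values", call. = FALSE)
  stats::ecdf(values)
}

#' First-order stochastic dominance check
#'
#' Distribution `a` first-order stochastically dominates `b` when
#' `F_a(x) <= F_b(x)` for all `x` - `a` puts weakly more mass on high values.
#' Because empirical CDFs are step functions that only change at sample
#' points, evaluating `F_a - F_b` on the union of the two samples (plus any
#' extra grid points supplied) is exact. The verdict allows violations up to
#' `eps`, so near-coincident CDFs still report weak dominance with the
#' violation magnitude logged.
#'
#' @param a_values,b_values Nonempty numeric samples.
#' @param eps Tolerance for CDF violations (default 0.01).
#' @param grid Optional extra evaluation points.
#' @return A `dominance_result`: `holds` (a FOSD b under `eps`),
#'   `max_violation` (largest positive value of `F_a - F_b`, 0 if none), and
#'   the evaluation `grid`.
#' @export
fosd_check <- function(a_values, b_values, eps = 0.01, grid = NULL) {
  a_values <- a_values[!is.na(a_values)]
  b_values <- b_values[!is.na(b_values)]
  if (length(a_values) == 0 || length(b_values) == 0)
    stop("both samples must be nonempty", call. = FALSE)
  pts <- sort(unique(c(a_values, b_values, grid)))
  Fa <- index_ecdf(a_values)
  Fb <- index_ecdf(b_values)
  diff <- Fa(pts) - Fb(pts)
  max_violation <- max(c(0, diff[diff > 0]))
  structure(list(holds = max_violation <= eps,
                 max_violation = max_violation,
                 eps = eps,
                 grid = pts),
            class = "dominance_result")
}

#' Pairwise dominance comparison of the four indices
#'
#' Checks whether the predicted-stress index first-order dominates each
#' COVID-exposure score (all four indices share the 0.25-1 scale).
#'
#' @param stress Predicted stress index values.
#' @param exposure_scores Named list of exposure score vectors.
#' @param eps Tolerance passed to [fosd_check()].
#' @return Data frame: `comparison`, `holds`, `max_violation`.
#' @export
dominance_table <- function(stress, exposure_scores, eps = 0.01) {
  rows <- lapply(names(exposure_scores), function(nm) {
    res <- fosd_check(stress, exposure_scores[[nm]], eps = eps)
    data.frame(comparison = paste0("stress_vs_", nm),
               holds = res$holds, max_violation = res$max_violation)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.dominance_result <- function(x, ...) {
  cat(sprintf("FOSD check: holds = %s (max violation %.4f, eps %.3f)\n",
              x$holds, x$max_violation, x$eps))
  invisible(x)
}
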
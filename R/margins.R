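#' Build a synthetic population-margins table
#'
#' Produces the gender x age-band x macro-region cell counts used for
#' post-stratification, one row per cell per country. The real analysis would
#' take these margins from official population statistics; here they are
#' generated so the projection step is testable end to end. By default cells
#' are uniform within country (equal counts, adjusted so they sum exactly to
#' the configured population total). Alternatively the margins can be made
#' proportional to the composition of a sample, in which case all
#' post-stratification weights collapse to 1.
#'
#' @param population_totals Named vector of adult (18-75) population totals
#'   per country. Defaults approximate the three study countries.
#' @param proportional_to Optional survey dataset; if given, cell counts are
#'   proportional to the sample's cell composition instead of uniform.
#' @return A `data.frame` with columns `country`, `gender`, `age_band`,
#'   `region`, `count`; every cell has a positive count and counts sum to the
#'   configured totals per country.
#' @export
synthetic_margins <- function(population_totals = c(IT = 44.3e6, ES = 34.7e6,
                                                    UK = 48.9e6),
                              proportional_to = NULL) {
  stopifnot(all(c("IT", "ES", "UK") %in% names(population_totals)),
            all(population_totals > 0))
  bands <- c("18-35", "36-55", "56-75")
  out <- do.call(rbind, lapply(c("IT", "ES", "UK"), function(cty) {
    cells <- expand.grid(gender = c("F", "M"), age_band = bands,
                         region = region_codes(cty),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    total <- population_totals[[cty]]
    if (is.null(proportional_to)) {
      counts <- rep(floor(total / nrow(cells)), nrow(cells))
      counts[seq_len(total - sum(counts))] <- counts[seq_len(total - sum(counts))] + 1
    } else {
      smp <- proportional_to[proportional_to$country == cty, , drop = FALSE]
      key <- paste(smp$gender, age_band(smp$age), smp$region)
      tab <- table(key)
      counts <- as.numeric(tab[paste(cells$gender, cells$age_band, cells$region)])
      if (anyNA(counts) || any(counts == 0))
        stop("sample has empty cells; cannot build proportional margins",
             call. = FALSE)
      counts <- counts / sum(counts) * total
    }
    data.frame(country = cty, cells, count = counts,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Post-stratification weights
#'
#' Computes one weight per respondent so that, within each country, the
#' weighted share of every gender x age-band x macro-region cell equals the
#' cell's population share from the margins table. The raw weight is
#' (population share of cell) / (sample share of cell), normalized to mean 1
#' within country.
#'
#' If a cell has positive population count but no sampled respondent, the
#' region dimension is collapsed first (margins aggregated over regions within
#' country), then the age-band dimension; if a gender cell is still empty the
#' function errors, listing the offending cells.
#'
#' @param data A survey dataset with `country`, `gender`, `age`, `region`.
#' @param margins Margins table as from [synthetic_margins()].
#' @return Numeric vector of positive weights aligned with `data` rows, mean 1
#'   within each country; attribute `"collapsed"` records any collapsing.
#' @export
poststratify <- function(data, margins) {
  stopifnot(all(c("country", "gender", "age_band", "region", "count") %in%
                  names(margins)))
  w <- rep(NA_real_, nrow(data))
  collapsed <- character(0)
  for (cty in unique(data$country)) {
    idx <- which(data$country == cty)
    mg <- margins[margins$country == cty, , drop = FALSE]
    if (nrow(mg) == 0)
      stop(sprintf("margins table has no rows for country %s", cty),
           call. = FALSE)
    dims <- list(
      full = c("gender", "age_band", "region"),
      no_region = c("gender", "age_band"),
      gender_only = "gender"
    )
    smp_key_all <- data.frame(
      gender = data$gender[idx],
      age_band = as.character(age_band(data$age[idx])),
      region = data$region[idx],
      stringsAsFactors = FALSE
    )
    wi <- NULL
    for (lev in names(dims)) {
      vars <- dims[[lev]]
      pop <- stats::aggregate(mg$count,
                              by = mg[vars],
                              FUN = sum)
      names(pop)[ncol(pop)] <- "count"
      pop_key <- do.call(paste, pop[vars])
      smp_key <- do.call(paste, smp_key_all[vars])
      smp_tab <- table(smp_key)
      missing_cells <- pop_key[pop$count > 0 & !(pop_key %in% names(smp_tab))]
      if (length(missing_cells) == 0) {
        pop_share <- pop$count / sum(pop$count)
        names(pop_share) <- pop_key
        smp_share <- as.numeric(smp_tab) / length(idx)
        names(smp_share) <- names(smp_tab)
        wi <- pop_share[smp_key] / smp_share[smp_key]
        if (lev != "full")
          collapsed <- c(collapsed, sprintf("%s: collapsed to %s", cty,
                                            paste(vars, collapse = " x ")))
        break
      }
      if (lev == "gender_only")
        stop(sprintf("empty sample cells in %s even after collapsing: %s",
                     cty, paste(missing_cells, collapse = ", ")),
             call. = FALSE)
    }
    w[idx] <- wi / mean(wi)
  }
  attr(w, "collapsed") <- collapsed
  w
}

#' Project the high-risk share to the population
#'
#' Weighted per-country high-risk shares plus a population-weighted pooled
#' share across countries.
#'
#' @param indicator Logical/0-1 vector of high-risk classifications.
#' @param weights Post-stratification weights aligned with `indicator`.
#' @param country Country code per respondent.
#' @param country_populations Named vector of population totals used to pool
#'   the per-country shares.
#' @return Named numeric vector with one share per country and a `pooled`
#'   entry, on the proportion (0-1) scale.
#' @export
project_high_risk_share <- function(indicator, weights, country,
                                    country_populations = c(IT = 44.3e6,
                                                            ES = 34.7e6,
                                                            UK = 48.9e6)) {
  if (length(indicator) != length(weights) ||
      length(indicator) != length(country))
    stop("indicator, weights and country must have equal length", call. = FALSE)
  ctys <- intersect(names(country_populations), unique(country))
  shares <- vapply(ctys, function(cty) {
    i <- country == cty
    sum(weights[i] * as.numeric(indicator[i])) / sum(weights[i])
  }, numeric(1))
  pooled <- sum(shares * country_populations[ctys]) /
    sum(country_populations[ctys])
  c(shares, pooled = pooled)
}
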
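#' Generate synthetic survey microdata
#'
#' Draws a respondent-level dataset with the randomized-arm structure and
#' correlation structure the downstream analyses assume. The data-generating
#' process is:
#'
#' * A latent economic vulnerability `V ~ N(0, 1)` per respondent. Higher
#'   vulnerability implies (monotonically) lower income, education and
#'   financial buffer, higher unemployment, income-loss and stress-event
#'   probability, and less living space.
#' * A mental-health latent `M = beta * V + eps`, `eps ~ N(0, noise_sd)`.
#'   Each of the eight Likert items adds item-specific noise to `M` and is cut
#'   at fixed latent thresholds into categories 1-4.
#' * Agreement with sensitive statement k is
#'   `Bernoulli(plogis(qlogis(p_k) + gamma * V))`.
#' * The four control items are independent Bernoulli draws with the
#'   configured prevalences; the item count in each arm is the sum of the
#'   agreements with the items that arm is shown (4 control items in the
#'   control arm, 4 + 1 sensitive in treatment arms). No design effect unless
#'   injection is switched on.
#' * In the direct arm a respondent who agrees with sensitive statement k
#'   admits it with probability `1 - liar_rate[k]`; disagreeing respondents
#'   always report disagreement.
#' * COVID-exposure blocks (comorbidities + self-rated health, quarantine
#'   compliance obstacles, health-seeking behaviour) are each driven by their
#'   own one-dimensional latent factor so that a one-component PCA summary is
#'   well posed.
#'
#' Arm allocation is exact (counts rounded from `arm_shares`, order
#' randomized within country). Identical seeds give byte-identical output.
#'
#' @param config A [survey_config()] object.
#' @return A `data.frame` with one row per respondent. Columns: `id`,
#'   `country`, `gender`, `age`, `region`, `arm`, `item_count` (NA in the
#'   direct arm), `direct_ctrl1..4` and `direct_sens1..2` (NA outside the
#'   direct arm), socio-economic covariates (`income_category`, `unemployed`,
#'   `married`, `homeowner`, `living_area`, `household_size`,
#'   `children_school`, `education`, `buffer_stock`, `stress_events`,
#'   `income_loss`), mental-health items `mh1..mh8` in 1-4, susceptibility
#'   items (`comorb_diabetes`, `comorb_hypertension`, `comorb_asthma`,
#'   `comorb_cardio`, `comorb_cancer`, `health_selfrated`), vulnerability
#'   items `vuln1..4`, and behaviour items (`contacted_doctor`,
#'   `contacted_authorities`, `sought_test`).
#' @export
generate_survey <- function(config = survey_config()) {
  if (!inherits(config, "survey_config"))
    stop("config must be created with survey_config()", call. = FALSE)
  set.seed(config$seed)

  countries <- c("IT", "ES", "UK")
  n_cty <- config$n_per_country
  n <- sum(n_cty)
  country <- rep(countries, n_cty)

  arm <- unlist(lapply(seq_along(countries), function(i) {
    sample(allocate_arms(n_cty[i], config$arm_shares))
  }), use.names = FALSE)

  gender <- sample(c("F", "M"), n, replace = TRUE)
  age <- sample(18:75, n, replace = TRUE)
  region <- unlist(lapply(seq_along(countries), function(i) {
    sample(region_codes(countries[i]), n_cty[i], replace = TRUE)
  }), use.names = FALSE)

  V <- stats::rnorm(n)

  # Socio-economic covariates, all monotone in latent vulnerability V.
  income_category <- cut_ordinal(-V + stats::rnorm(n, 0, 0.9), 10L)
  unemployed <- stats::rbinom(n, 1, stats::plogis(-1.8 + 0.8 * V))
  married <- stats::rbinom(n, 1, 0.55)
  homeowner <- stats::rbinom(n, 1, stats::plogis(0.4 - 0.6 * V))
  living_area <- pmax(20, round(95 - 14 * V + stats::rnorm(n, 0, 25)))
  household_size <- 1L + stats::rbinom(n, 6, stats::plogis(-0.8 + 0.15 * V))
  children_school <- stats::rbinom(n, 3, stats::plogis(-1.4 + 0.25 * V))
  education <- cut_ordinal(-V + stats::rnorm(n, 0, 1.1), 5L)
  buffer_stock <- cut_ordinal(-V + stats::rnorm(n, 0, 0.8), 5L)
  stress_events <- stats::rbinom(n, 8, stats::plogis(-1.1 + 0.7 * V))
  income_loss <- stats::rbinom(n, 1, stats::plogis(-0.4 + 0.8 * V))

  # Mental-health items: shared latent plus item noise, fixed thresholds.
  beta <- config$vulnerability_loading
  M <- beta * V + stats::rnorm(n, 0, config$noise_sd)
  total_sd <- sqrt(beta^2 + config$noise_sd^2 + config$item_noise_sd^2)
  thr <- stats::qnorm(config$mh_thresholds, mean = 0, sd = total_sd)
  mh <- vapply(1:8, function(j) {
    lat <- M + stats::rnorm(n, 0, config$item_noise_sd)
    1L + findInterval(lat, thr)
  }, integer(n))
  colnames(mh) <- paste0("mh", 1:8)

  # Sensitive-statement agreement (latent, independent of the arm shown).
  gamma <- config$sensitivity_loading
  z <- vapply(1:2, function(k) {
    p <- config$true_support[k]
    stats::rbinom(n, 1, stats::plogis(stats::qlogis(p) + gamma * V))
  }, integer(n))

  # Control items; optional injected design effect in treatment arms.
  prev <- matrix(config$control_item_prevalences, nrow = n, ncol = 4,
                 byrow = TRUE)
  if (config$design_effect_injection) {
    shifted <- arm %in% c("T1", "T2")
    prev[shifted, ] <- pmax(0.01, prev[shifted, ] - config$injection_shift)
  }
  ctrl <- matrix(stats::rbinom(n * 4L, 1, prev), nrow = n)

  item_count <- rowSums(ctrl)
  item_count[arm == "T1"] <- item_count[arm == "T1"] + z[arm == "T1", 1]
  item_count[arm == "T2"] <- item_count[arm == "T2"] + z[arm == "T2", 2]
  item_count[arm == "direct"] <- NA_integer_

  # Direct arm: all six statements shown individually; liars deny agreement.
  direct <- arm == "direct"
  direct_ctrl <- matrix(NA_integer_, n, 4)
  direct_ctrl[direct, ] <- ctrl[direct, ]
  admit <- vapply(1:2, function(k) {
    stats::rbinom(n, 1, 1 - config$liar_rate[k])
  }, integer(n))
  direct_sens <- matrix(NA_integer_, n, 2)
  direct_sens[direct, ] <- (z * admit)[direct, ]

  # COVID-exposure blocks, each with a one-dimensional latent factor.
  H <- stats::rnorm(n)  # frailty: drives comorbidity and poor health
  comorb_int <- c(-2.4, -2.0, -2.3, -2.2, -2.8)
  comorb <- vapply(comorb_int, function(a) {
    stats::rbinom(n, 1, stats::plogis(a + 0.9 * H + 0.035 * (age - 46)))
  }, integer(n))
  colnames(comorb) <- paste0("comorb_", c("diabetes", "hypertension",
                                          "asthma", "cardio", "cancer"))
  health_selfrated <- cut_ordinal(H + 0.02 * (age - 46) + stats::rnorm(n, 0, 0.7), 5L)

  U <- stats::rnorm(n)  # obstacles to full quarantine compliance
  vuln <- vapply(1:4, function(j) {
    cut_ordinal(U + stats::rnorm(n, 0, 0.8), 4L)
  }, integer(n))
  colnames(vuln) <- paste0("vuln", 1:4)

  B <- stats::rnorm(n)  # propensity to seek care/testing
  contacted_doctor <- stats::rbinom(n, 1, stats::plogis(-1.4 + 1.3 * B))
  contacted_authorities <- stats::rbinom(n, 1, stats::plogis(-1.7 + 1.3 * B))
  sought_test <- stats::rbinom(n, 1, stats::plogis(-1.5 + 1.3 * B))

  out <- data.frame(
    id = seq_len(n),
    country = country,
    gender = gender,
    age = age,
    region = region,
    arm = arm,
    item_count = item_count,
    direct_ctrl1 = direct_ctrl[, 1], direct_ctrl2 = direct_ctrl[, 2],
    direct_ctrl3 = direct_ctrl[, 3], direct_ctrl4 = direct_ctrl[, 4],
    direct_sens1 = direct_sens[, 1], direct_sens2 = direct_sens[, 2],
    income_category = income_category,
    unemployed = unemployed,
    married = married,
    homeowner = homeowner,
    living_area = living_area,
    household_size = household_size,
    children_school = children_school,
    education = education,
    buffer_stock = buffer_stock,
    stress_events = stress_events,
    income_loss = income_loss,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(mh), as.data.frame(comorb),
               health_selfrated = health_selfrated, as.data.frame(vuln),
               contacted_doctor = contacted_doctor,
               contacted_authorities = contacted_authorities,
               sought_test = sought_test)
  class(out) <- c("survey_data", "data.frame")
  attr(out, "config") <- config
  out
}

# Exact arm counts from target shares: floor, then hand out remainders to the
# arms with the largest fractional parts.
allocate_arms <- function(n, shares) {
  raw <- n * shares
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    top <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1
  }
  rep(names(shares), counts)
}

# Discretize a continuous latent into k ordered categories at its empirical
# quantiles (equal-mass bins).
cut_ordinal <- function(x, k) {
  q <- stats::quantile(x, probs = seq_len(k - 1) / k, names = FALSE)
  1L + findInterval(x, q)
}

#' Subset a survey dataset to an analysis scope
#'
#' @param data A survey dataset.
#' @param scope `"pooled"` for all countries or one of `"IT"`, `"ES"`, `"UK"`.
#' @return The subset (all rows when pooled).
#' @export
filter_scope <- function(data, scope = "pooled") {
  scope <- match.arg(scope, c("pooled", "IT", "ES", "UK"))
  if (scope == "pooled") data else data[data$country == scope, , drop = FALSE]
}
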
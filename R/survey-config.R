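#' Configuration for the synthetic survey generator
#'
#' Bundles and validates every knob of the synthetic data-generating process:
#' sample sizes, randomized-arm allocation, true support for the two sensitive
#' statements, the lying mechanism under direct questioning, and the latent
#' economic-vulnerability structure that links covariates to mental health.
#'
#' The defaults reproduce the survey design the package targets: three
#' countries (Italy N = 3,504, Spain N = 3,524, UK N = 3,523), four randomized
#' arms allocated 30/30/30/10 (control, treatment one, treatment two, direct
#' questioning), four uncontroversial control statements and two sensitive
#' ones.
#'
#' @param n_per_country Named integer vector of respondents per country
#'   (names `IT`, `ES`, `UK`).
#' @param arm_shares Named numeric vector of allocation proportions for arms
#'   `control`, `T1`, `T2`, `direct`; must sum to 1.
#' @param true_support Length-2 vector: population agreement probability for
#'   sensitive statements 1 and 2.
#' @param control_item_prevalences Agreement probabilities for the four
#'   control statements. Defaults mix polarized opinions with one
#'   high-consensus health item to avoid ceiling effects.
#' @param liar_rate Length-2 vector: probability that a respondent who agrees
#'   with the sensitive statement denies it under direct questioning.
#' @param vulnerability_loading Effect (beta >= 0) of the latent economic
#'   vulnerability on the mental-health latent.
#' @param sensitivity_loading Effect (gamma) of latent vulnerability on the
#'   log-odds of agreeing with each sensitive statement; 0 means agreement is
#'   independent of vulnerability.
#' @param noise_sd Standard deviation (> 0) of the person-level disturbance of
#'   the mental-health latent.
#' @param item_noise_sd Standard deviation of the item-specific measurement
#'   noise added to the mental-health latent before discretization. The
#'   default yields, after discretization, an observed inter-item correlation
#'   near 0.56 and hence a Cronbach's alpha near 0.91 for eight items.
#' @param mh_thresholds Cumulative probabilities at which the per-item latent
#'   is cut into the four Likert categories. The default puts about 58% of
#'   answers at category 2 or above, matching the symptom-prevalence range
#'   typical of lockdown surveys; `c(0.25, 0.5, 0.75)` gives uniform items.
#' @param design_effect_injection If `TRUE`, the presence of a sensitive item
#'   shifts control-item agreement down by `injection_shift` in the treatment
#'   arms, violating the list-experiment design assumption (used for power
#'   analyses of the design-effect test).
#' @param injection_shift Size of the injected drop in control-item agreement
#'   probability when `design_effect_injection` is on.
#' @param seed Integer seed; the generator is fully deterministic given it.
#'
#' @return A validated list of class `"survey_config"`.
#' @export
survey_config <- function(n_per_country = c(IT = 3504L, ES = 3524L, UK = 3523L),
                          arm_shares = c(control = 0.30, T1 = 0.30,
                                         T2 = 0.30, direct = 0.10),
                          true_support = c(0.62, 0.70),
                          control_item_prevalences = c(0.35, 0.45, 0.90, 0.55),
                          liar_rate = c(0.09, 0.05),
                          vulnerability_loading = 0.6,
                          sensitivity_loading = 0,
                          noise_sd = 0.8,
                          item_noise_sd = 0.75,
                          mh_thresholds = c(0.42, 0.68, 0.88),
                          design_effect_injection = FALSE,
                          injection_shift = 0.3,
                          seed = 1L) {
  stopifnot(length(n_per_country) == 3L)
  if (is.null(names(n_per_country))) names(n_per_country) <- c("IT", "ES", "UK")
  if (!all(c("IT", "ES", "UK") %in% names(n_per_country)))
    stop("n_per_country must be named IT, ES, UK", call. = FALSE)
  if (any(n_per_country < 1) || any(n_per_country != round(n_per_country)))
    stop("n_per_country must be positive integers", call. = FALSE)

  if (length(arm_shares) != 4L)
    stop("arm_shares must have four entries (control, T1, T2, direct)",
         call. = FALSE)
  if (is.null(names(arm_shares)))
    names(arm_shares) <- c("control", "T1", "T2", "direct")
  if (abs(sum(arm_shares) - 1) > 1e-8)
    stop("arm_shares must sum to 1", call. = FALSE)
  if (any(arm_shares < 0)) stop("arm_shares must be non-negative", call. = FALSE)

  check_prob <- function(x, what) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
  check_prob(true_support, "true_support")
  check_prob(control_item_prevalences, "control_item_prevalences")
  check_prob(liar_rate, "liar_rate")
  check_prob(mh_thresholds, "mh_thresholds")
  stopifnot(length(true_support) == 2L, length(liar_rate) == 2L,
            length(control_item_prevalences) == 4L,
            length(mh_thresholds) == 3L)
  if (any(control_item_prevalences <= 0) || any(control_item_prevalences >= 1))
    stop("control_item_prevalences must lie strictly inside (0, 1)",
         call. = FALSE)
  if (vulnerability_loading < 0)
    stop("vulnerability_loading must be >= 0", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (item_noise_sd < 0) stop("item_noise_sd must be >= 0", call. = FALSE)
  if (injection_shift < 0 || injection_shift > 1)
    stop("injection_shift must lie in [0, 1]", call. = FALSE)

  structure(list(
    n_per_country = as.integer(n_per_country[c("IT", "ES", "UK")]),
    arm_shares = arm_shares[c("control", "T1", "T2", "direct")],
    true_support = true_support,
    control_item_prevalences = control_item_prevalences,
    liar_rate = liar_rate,
    vulnerability_loading = vulnerability_loading,
    sensitivity_loading = sensitivity_loading,
    noise_sd = noise_sd,
    item_noise_sd = item_noise_sd,
    mh_thresholds = mh_thresholds,
    design_effect_injection = isTRUE(design_effect_injection),
    injection_shift = injection_shift,
    seed = as.integer(seed)
  ), class = "survey_config")
}

#' Macro-region codes used for post-stratification
#'
#' Four macro-regions for Italy, five for Spain and five for the UK.
#'
#' @param country One of `"IT"`, `"ES"`, `"UK"`.
#' @return Character vector of region labels.
#' @export
region_codes <- function(country) {
  switch(match.arg(country, c("IT", "ES", "UK")),
    IT = c("North", "Centre", "South", "Isles"),
    ES = c("MadridCentre", "BarcelonaWest", "North", "CentreEast", "South"),
    UK = c("EastMidlands", "London", "South", "North", "ScotWalesNI"))
}

#' Age bands used for post-stratification
#'
#' @param age Numeric vector of ages in years (18-75).
#' @return Factor with levels `18-35`, `36-55`, `56-75`.
#' @export
age_band <- function(age) {
  cut(age, breaks = c(17, 35, 55, 75), labels = c("18-35", "36-55", "56-75"))
}
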
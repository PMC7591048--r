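---
title: "Methods: list-experiment elicitation and mental-health risk projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: list-experiment elicitation and mental-health risk projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `econstress`, the
assumptions they rest on, the synthetic data-generating process used to
validate them, and the design choices made where the methodology left room.

## 1. The list experiment

### Model

Respondents are randomized into four arms. The control arm sees `J = 4`
uncontroversial statements; treatment arms T1 and T2 see the same four plus
one sensitive statement; the direct arm is asked about all six statements
individually. Arms report only the *number* of statements they agree with
(except the direct arm), which shields individual answers. Under
randomization,

* `support = E[count | T_k] - E[count | control]` identifies the share
  agreeing with sensitive statement k (difference-in-means estimator, Welch
  standard error), and
* OLS of the count on a treatment dummy plus covariates gives the same
  estimand with residual variance absorbed by covariates. With no
  covariates the OLS coefficient *equals* the difference in means, a tested
  identity. Standard errors are HC1 (heteroskedasticity-robust): item counts
  are bounded sums of Bernoulli variables, so homoskedasticity has no
  justification. The default adjustment set is a female dummy, age, marital
  status, unemployment, household size, children of school age, income
  level, education, homeownership, living area, and country dummies in
  pooled fits.
* `SDB = support_list - support_direct`. The two subsamples are disjoint, so
  the variance of the contrast is the sum of the variances.

The direct arm is deliberately small (10%): a binomial proportion at
`n ≈ 1,000` has a standard error an order of magnitude below the
list-experiment contrast, so sample is better spent on the treatment arms.

### Identifying assumptions and diagnostics

The estimator assumes **no design effect** (adding the sensitive item does
not change answers to the control items) and **no liars** (counts are
truthful). The second is untestable. The first is diagnosed through the
estimated respondent-type proportions: with `G` and `H` the control- and
treatment-arm count CDFs,

    pi(y, 1) = G(y) - H(y),      pi(y, 0) = H(y) - G(y - 1),   y = 0..J.

These sum to one by telescoping, and under no design effect all are
nonnegative. `pi(J, 1) = 1 - H(J)` and `pi(0, 0) = H(0)` are nonnegative by
construction, so the test covers the remaining `2(J+1) - 2 = 8` proportions
with one-sided normal tests, Bonferroni-corrected. The correction makes the
test conservative: its simulated type-I error at nominal 5% is well below
5%, which the calibration tests verify, along with >50% power against a 0.3
drop in control-item agreement.

Covariate balance is checked per covariate with a joint test across the four
arms: one-way ANOVA for numeric covariates, chi-squared for categorical
ones. With many covariates some rejections at 5% are expected under sound
randomization.

## 2. The stress/anxiety/depression index

The instrument is an 8-item adaptation of DASS-21/SASRQ, each item on a 1-4
frequency scale for the previous week. The index is `mean(items) / 4`,
bounded in `[0.25, 1]`, reaching 0.25 only when all items are 1 and 1 only
when all are 4. Missing items: respondents answering at least 6 of 8 get a
prorated mean; below that they are excluded (the instrument is no longer
comparable), with excluded ids logged. Reliability is Cronbach's alpha,
`J/(J-1) * (1 - sum var_j / var_total)`, cross-checked in the tests against
the closed form `J*rho / (1 + (J-1)*rho)` for equicorrelated items.
Associations with economic covariates use Spearman rather than Pearson
correlations: the predictors are largely ordinal, and rank correlations are
robust to response error and atypical values. P-values use the t
approximation with average ranks for ties.

## 3. Risk projection

A regression random forest (550 trees, `mtry = 3`, bootstrap samples of size
n — the only stated hyperparameters are the tree count and the regression
type; the rest are the field's defaults, recorded in the fitted object)
predicts the index from nine economic predictors: household income,
unemployment, homeownership, living area, household size, children of
school age, financial buffer stock, negative events in the previous week,
and income loss. Ordinal predictors enter as integers. Predictions are
clipped to the outcome's `[0.25, 1]` range. High risk is an *inclusive*
threshold: predicted index `>= 0.5`.

Classification uses in-sample predictions, guarded by `holdout_stability()`:
for learning fractions 15/25/33/50% the forest is refit on the fraction and
its out-of-sample predictions are rank-correlated with the full-sample
model's. High correlations indicate the in-sample classification is not an
overfitting artifact. The out-of-bag MSE curve by tree count is recorded to
check convergence within the 550 trees.

Post-stratification weights are `w = pop_share(cell) / sample_share(cell)`
over gender x age band x macro-region cells (4 regions for Italy, 5 each
for Spain and the UK), normalized to mean 1 within country; weighted cell
shares then reproduce population shares exactly (tested to 1e-10). If a
populated cell has no sampled respondent the region dimension is collapsed
first, then age band — region is the dimension least related to the outcome
here — and an error is raised only if a gender cell is still empty. The
pooled high-risk share weights the per-country shares by population totals;
weights are normalized within country *before* pooling, matching the
interpretation of a population-weighted average of country estimates.

## 4. Exposure PCA

Each of the three exposure blocks — susceptibility (age, five comorbidity
flags, self-rated health), vulnerability (quarantine-compliance obstacles),
behavioural response (contacted doctor/authorities, sought testing) — is
summarized by the first principal component of the item *correlation*
matrix, so items are implicitly standardized and the score is invariant to
affine rescaling of any item. Adequacy is assessed by the KMO statistic
computed from the inverse correlation matrix (anti-image partial
correlations); the tests verify it against a brute-force partial-correlation
computation via regression residuals, and the eigenvalues against a
power-iteration oracle. Components are retained by the strict
eigenvalue > 1 rule; if even the first eigenvalue fails it, the score is
still produced from component 1 but flagged. Binary and ordinal items are
treated as numeric — polychoric correlations are out of scope.

Two conventions the method itself does not pin down:

* **Sign**: an eigenvector is defined up to sign, so the first component is
  oriented to load positively on a designated anchor item (default: the
  block's first item, e.g. a comorbidity flag for susceptibility), making
  the score increase with exposure.
* **Rescaling**: the score is mapped to `[0.25, 1]` by linear min-max on the
  observed sample, making it comparable with the stress index's scale.

## 5. Stochastic dominance

Index A first-order dominates B when `F_A(x) <= F_B(x)` everywhere.
Empirical CDFs are step functions changing only at sample points, so
evaluating on the union of both samples is *exact*; the tests confirm
agreement with a 10,000-point dense-grid oracle. The verdict tolerates
violations up to `eps = 0.01` so that near-coincident CDFs report weak
dominance with the violation magnitude logged; `eps` is configurable and the
check is purely descriptive — no inferential dominance test is applied.

## 6. The synthetic survey generator

The generator emulates the study design so the pipeline is testable without
the original microdata: 3,504/3,524/3,523 respondents for IT/ES/UK, exact
30/30/30/10 arm allocation, 4 control + 2 sensitive statements.

The generative contract (all tested):

* Latent vulnerability `V ~ N(0,1)`; covariates are monotone in `V` through
  logistic or quantile-cut links (lower income/education/buffer, more
  unemployment, stress events and income loss, less living space).
* Mental-health latent `M = beta*V + eps`; each item adds its own noise and
  is cut at fixed thresholds. Defaults: `beta = 0.6`, `noise_sd = 0.8`,
  `item_noise_sd = 0.75` — chosen so the *discretized* items have a
  Cronbach's alpha near 0.91, the reliability typical of this instrument
  (the latent-scale calculation would ignore ordinal attenuation). Cut
  points default to cumulative probabilities (0.42, 0.68, 0.88), putting
  ~58% of answers at category 2+ as lockdown surveys report, rather than
  uniform categories which would force 75% and centre the index at 0.625.
* Sensitive agreement is `Bernoulli(plogis(qlogis(p_k) + gamma*V))` with
  defaults `p = (0.62, 0.70)`; under direct questioning an agreeing
  respondent admits it with probability `1 - lambda_k`, defaults
  `lambda = (0.09, 0.05)` — the under-reporting magnitudes typical of mildly
  sensitive policy statements.
* Control items are independent Bernoullis with prevalences
  (0.35, 0.45, 0.90, 0.55): polarized opinions plus one high-consensus
  health item, avoiding ceiling effects on the 0-4 count.
* No design effect unless injection is on, in which case treatment-arm
  control-item prevalences drop by 0.3 (for power studies).
* Each exposure block has its own one-dimensional latent factor, so a
  single-component PCA summary is well specified.

What it does **not** emulate: the questionnaire wording, panel recruitment
and non-response, the covariate *joint* distribution (only monotone links to
`V` are contractual), country-level heterogeneity in support, and any
design effect in the real instrument. Passing tests therefore show the
estimators are correct under the stated design, not that the original
point estimates are reproducible — those require the deposited microdata.

## 7. Problem sizes and determinism

Test simulations use the full design size (n = 10,551) where the property
concerns the study scale — estimator recovery, CI coverage over 200
replicates, design-effect calibration over 100 replicates — and reduced
sizes (600-2,100 per country, 60-150 trees) where the property is
structural. All stochastic steps derive from explicit seeds; the pipeline
(generation through dominance) is byte-identical across runs at a fixed
seed, which the acceptance-style determinism test asserts via `identical()`
on every numeric output.

## 8. Known limitations

* In-sample classification inherits the forest's smoothing: extreme indices
  are pulled toward the centre, so the high-risk share is a model-based
  quantity, not a raw prevalence.
* The dominance check is descriptive; sampling noise near-ties are handled
  by `eps`, not by inference.
* KMO and PCA on binary items understate adequacy relative to polychoric
  treatment.
* No uncertainty is attached to the projected high-risk share; the
  projection is a point estimate by design.
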
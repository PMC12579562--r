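#' Covariate specification helpers for the registry generator
#'
#' Each covariate in a generator configuration is described by one of these
#' constructors, giving per-group (dual / single) distribution parameters.
#' Continuous covariates use a log-normal (parameterised by its median and
#' log-scale spread, so registry-style "median (IQR)" summaries map directly
#' onto parameters) or a truncated normal (for bounded quantities such as ages
#' and percentile scores). Categorical covariates and flags are parameterised
#' by per-group level probabilities.
#'
#' @param median_dual,median_single medians of the log-normal by group.
#' @param sdlog_dual,sdlog_single log-scale standard deviations; for a summary
#'   "median (q1, q3)" the moment-matched value is `(log(q3) - log(q1)) /
#'   (2 * qnorm(0.75))`.
#' @param mean_dual,mean_single,sd_dual,sd_single location and scale of the
#'   (pre-truncation) normal by group.
#' @param lower,upper truncation bounds.
#' @param levels character vector of category labels.
#' @param p_dual,p_single probability vectors over `levels` (summing to 1), or
#'   scalar event probabilities for flags.
#' @param p0_dual,p0_single point mass at zero for zero-inflated percent scales.
#' @param shape1,shape2 Beta shape parameters for the positive part (scaled to
#'   0-100).
#' @param loading correlation loading in [-1, 1] on the generator's single
#'   latent "marginality" factor (Gaussian copula). Loadings shape the joint
#'   distribution only; each covariate's per-group marginal is exactly the
#'   configured one. For categorical covariates the listed level order is the
#'   copula order (higher latent value maps to later levels); for flags a
#'   positive loading makes the flag more likely at high latent values.
#' @return A covariate specification list consumed by [registry_config()].
#' @name covariate-specs
NULL

#' @rdname covariate-specs
#' @export
cov_lognormal <- function(median_dual, sdlog_dual, median_single, sdlog_single,
                          loading = 0) {
  stopifnot(median_dual > 0, median_single > 0, sdlog_dual > 0, sdlog_single > 0)
  list(kind = "lognormal",
       dual = c(meanlog = log(median_dual), sdlog = sdlog_dual),
       single = c(meanlog = log(median_single), sdlog = sdlog_single),
       loading = check_loading(loading))
}

check_loading <- function(loading) {
  stopifnot(is.numeric(loading), length(loading) == 1,
            loading >= -1, loading <= 1)
  loading
}

#' @rdname covariate-specs
#' @export
cov_truncnorm <- function(mean_dual, sd_dual, mean_single, sd_single,
                          lower = -Inf, upper = Inf, loading = 0) {
  stopifnot(sd_dual > 0, sd_single > 0, lower < upper)
  list(kind = "truncnorm",
       dual = c(mean = mean_dual, sd = sd_dual),
       single = c(mean = mean_single, sd = sd_single),
       lower = lower, upper = upper, loading = check_loading(loading))
}

#' @rdname covariate-specs
#' @export
cov_categorical <- function(levels, p_dual, p_single, loading = 0) {
  stopifnot(length(levels) == length(p_dual), length(levels) == length(p_single))
  for (p in list(p_dual, p_single)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("category probabilities must be nonnegative and sum to 1",
           call. = FALSE)
  }
  list(kind = "categorical", levels = levels,
       dual = p_dual / sum(p_dual), single = p_single / sum(p_single),
       loading = check_loading(loading))
}

#' @rdname covariate-specs
#' @export
cov_flag <- function(p_dual, p_single, loading = 0) {
  stopifnot(p_dual >= 0, p_dual <= 1, p_single >= 0, p_single <= 1)
  list(kind = "flag", dual = p_dual, single = p_single,
       loading = check_loading(loading))
}

#' @rdname covariate-specs
#' @export
cov_zero_inflated_percent <- function(p0_dual, shape1_dual, shape2_dual,
                                      p0_single, shape1_single, shape2_single,
                                      loading = 0) {
  stopifnot(p0_dual >= 0, p0_dual <= 1, p0_single >= 0, p0_single <= 1)
  list(kind = "zero_inflated_percent",
       dual = c(p0 = p0_dual, shape1 = shape1_dual, shape2 = shape2_dual),
       single = c(p0 = p0_single, shape1 = shape1_single, shape2 = shape2_single),
       loading = check_loading(loading))
}

# Default covariate distributions, calibrated to published national-registry
# group summaries: log-normal/truncated-normal parameters are moment-matched
# to median (IQR); categorical probabilities are the published per-group level
# counts. Recipient sex and race/ethnicity are not part of the published group
# comparison; their (group-invariant) defaults are typical US deceased-donor
# kidney recipient proportions and exist to support the BMI imputation model.
#
# Loadings tie covariates to one latent donor/recipient "marginality" axis —
# strong for quality-derived indices (KDRI is computed from donor age and
# comorbidity; EPTS from recipient age, diabetes and dialysis history),
# moderate for logistics driven by organ quality (pumping, sharing breadth,
# CIT), negative where marginal-kidney recipients run lower (dialysis
# vintage, sensitization), zero where unrelated. Categorical level lists are
# in copula order (ascending marginality).
default_covariate_params <- function() {
  iqr_sdlog <- function(q1, q3) (log(q3) - log(q1)) / (2 * stats::qnorm(0.75))
  list(
    donor_age = cov_truncnorm(58, (65 - 50) / 1.349, 40, (51 - 29) / 1.349,
                              lower = 5, upper = 90, loading = 0.85),
    kdri = cov_lognormal(1.88, iqr_sdlog(1.56, 2.23), 1.21, iqr_sdlog(0.99, 1.50),
                         loading = 0.95),
    pump = cov_flag(736 / 1015, 75452 / 134933, loading = 0.23),
    donor_female = cov_flag(540 / 1015, 50486 / 134933, loading = 0.22),
    cit_hours = cov_lognormal(23, iqr_sdlog(17, 29), 18, iqr_sdlog(13, 23),
                              loading = 0.35),
    glomerulosclerosis = cov_categorical(
      c("no biopsy", "0-5%", "6-10%", "11-15%", "16-20%", ">20%"),
      c(168, 264, 157, 126, 102, 198) / 1015,
      c(67353, 50334, 10253, 3859, 1687, 1447) / 134933,
      loading = 0.5),
    inotropic_support = cov_flag(376 / 1015, 43687 / 134933, loading = 0.05),
    sharing = cov_categorical(
      c("local", "regional", "national"),
      c(480, 220, 315) / 1015,
      c(78823, 25498, 30612) / 134933, loading = 0.15),
    distance_miles = cov_lognormal(137, iqr_sdlog(29, 395), 90, iqr_sdlog(15, 211),
                                   loading = 0.05),
    recipient_age = cov_truncnorm(65, (70 - 59) / 1.349, 55, (64 - 44) / 1.349,
                                  lower = 18, upper = 90, loading = 0.58),
    epts = cov_truncnorm(68, (85 - 47) / 1.349, 51, (78 - 21) / 1.349,
                         lower = 0, upper = 100, loading = 0.32),
    dialysis_group = cov_categorical(
      c("preemptive", "<1y", "1-5y", "5-10y", ">=10y"),
      c(201, 107, 586, 106, 15) / 1015,
      c(19516, 6431, 58235, 42476, 8275) / 134933, loading = -0.33),
    pvd = cov_flag(156 / 1015, 15726 / 134933, loading = 0.09),
    renal_diagnosis = cov_categorical(
      c("retransplant", "glomerular", "polycystic", "other", "hypertensive",
        "diabetes"),
      c(9, 143, 70, 105, 251, 437) / 1015,
      c(10722, 24579, 9214, 17902, 31894, 40622) / 134933, loading = 0.25),
    bmi = cov_lognormal(27.4, iqr_sdlog(24.2, 31.3), 28.1, iqr_sdlog(24.4, 32.3),
                        loading = -0.09),
    cpra = cov_zero_inflated_percent(0.70, 0.6, 6, 0.50, 1, 1, loading = -0.63),
    abo_incompatible = cov_flag(13 / 1015, 2786 / 134933),
    hla_mismatch = cov_categorical(
      as.character(0:6),
      c(7, 9, 26, 109, 236, 398, 230) / 1015,
      c(6721, 1888, 6711, 19420, 37268, 43157, 19768) / 134933, loading = 0.28),
    induction = cov_categorical(
      c("lymphocyte_depletion", "combination", "il2ra"),
      c(782, 49, 223) / 1054,
      c(107392, 4189, 22223) / 133804, loading = 0.1),
    steroids_maintenance = cov_flag(759 / 1015, 97659 / 134933, loading = 0.03),
    recipient_female = cov_flag(0.39, 0.39),
    race = cov_categorical(
      c("white", "black", "hispanic", "asian", "other"),
      c(0.35, 0.30, 0.22, 0.09, 0.04),
      c(0.35, 0.30, 0.22, 0.09, 0.04))
  )
}

#' Generator configuration for synthetic transplant registries
#'
#' Bundles sample sizes, covariate distributions, true group effects on the
#' survival endpoints, baseline hazards, censoring and secondary-outcome rates
#' into a validated configuration object.
#'
#' The survival-time model: the all-cause graft failure time (first of graft
#' failure or death with a functioning graft) is exponential with hazard
#' `baseline_hazard["all_cause_graft"] * exp(group * true_log_hr["all_cause_graft"])`.
#' Each all-cause event is a graft failure with a group-specific cause
#' fraction chosen so the cause-specific (death-censored) graft-failure hazard
#' has exactly the configured death-censored hazard ratio; otherwise it is a
#' death with functioning graft. Deaths after graft failure occur at rate
#' `post_graftfail_death_hazard` (return-to-dialysis mortality). Both
#' tested endpoints (all-cause and death-censored graft survival) therefore
#' have exactly proportional hazards with the configured ratios; patient
#' survival is a mixture and only approximately proportional.
#'
#' Censoring is administrative (entry uniform over the accrual window, so
#' censoring time is uniform on (0, `max_followup_years`)) plus an independent
#' exponential loss-to-follow-up at `censor_rate` per year.
#'
#' @param n_dual,n_single group sizes (defaults: the published cohort sizes).
#' @param seed integer seed; generation is deterministic given the seed.
#' @param covariate_params named list of covariate specifications (see
#'   [cov_lognormal()] and friends).
#' @param true_log_hr named numeric: log hazard ratios (dual vs single) for
#'   `all_cause_graft` and `death_censored_graft`.
#' @param baseline_hazard named numeric: events per year in the single group
#'   for the same endpoints (defaults from the published 6-year survival:
#'   `-log(0.529)/6` all-cause, `-log(0.799)/6` death-censored).
#' @param post_graftfail_death_hazard death rate (per year) after graft loss.
#' @param censor_rate loss-to-follow-up rate per year (>= 0).
#' @param max_followup_years administrative follow-up horizon (study window).
#' @param outcome_probs named list with per-group probabilities `dgf`,
#'   `rejection_6m`, `rejection_1y`, each `c(dual=, single=)`.
#' @param creatinine_1y log-normal parameters for 1-year creatinine, per group.
#' @param los_days log-normal parameters for length of stay, per group.
#' @param missing_rates missing-completely-at-random rates for `bmi`,
#'   `cit_hours`, `los_days` (defaults mirror the published missing counts out
#'   of 135,948 records).
#' @param contamination_rates rates of records that violate the cohort filters
#'   (recipient under 18, living donor, en bloc, missing KDRI, missing
#'   survival); all zero by default.
#' @return An object of class `registry_config`.
#' @export
registry_config <- function(n_dual = 1015,
                            n_single = 134933,
                            seed = 1L,
                            covariate_params = default_covariate_params(),
                            true_log_hr = c(all_cause_graft = log(0.79),
                                            death_censored_graft = log(0.73)),
                            baseline_hazard = c(all_cause_graft = -log(0.529) / 6,
                                                death_censored_graft = -log(0.799) / 6),
                            post_graftfail_death_hazard = 0.15,
                            censor_rate = 0.02,
                            max_followup_years = 9.33,
                            outcome_probs = list(
                              dgf = c(dual = 399 / 1015, single = 964 / 3045),
                              rejection_6m = c(dual = 28 / 727, single = 122 / 2242),
                              rejection_1y = c(dual = 35 / 662, single = 148 / 1968)),
                            creatinine_1y = list(dual = c(median = 1.2, sdlog = 0.35),
                                                 single = c(median = 1.6, sdlog = 0.32)),
                            los_days = list(dual = c(median = 5, sdlog = 0.51),
                                            single = c(median = 5, sdlog = 0.42)),
                            missing_rates = c(bmi = 241 / 135948,
                                              cit_hours = 203 / 135948,
                                              los_days = 588 / 135948),
                            contamination_rates = c(age_lt18 = 0, living_donor = 0,
                                                    en_bloc = 0, missing_kdri = 0,
                                                    missing_survival = 0)) {
  cfg <- list(n_dual = as.integer(n_dual), n_single = as.integer(n_single),
              seed = as.integer(seed), covariate_params = covariate_params,
              true_log_hr = true_log_hr, baseline_hazard = baseline_hazard,
              post_graftfail_death_hazard = post_graftfail_death_hazard,
              censor_rate = censor_rate,
              max_followup_years = max_followup_years,
              outcome_probs = outcome_probs,
              creatinine_1y = creatinine_1y, los_days = los_days,
              missing_rates = missing_rates,
              contamination_rates = contamination_rates)
  class(cfg) <- "registry_config"
  validate_registry_config(cfg)
  cfg
}

validate_registry_config <- function(cfg) {
  if (cfg$n_dual < 0 || cfg$n_single < 0)
    stop("n_dual and n_single must be nonnegative", call. = FALSE)
  needed <- c("all_cause_graft", "death_censored_graft")
  if (!all(needed %in% names(cfg$true_log_hr)) ||
      !all(needed %in% names(cfg$baseline_hazard)))
    stop("true_log_hr and baseline_hazard must name endpoints ",
         paste(needed, collapse = ", "), call. = FALSE)
  if (any(cfg$baseline_hazard <= 0))
    stop("baseline hazards must be positive", call. = FALSE)
  if (cfg$max_followup_years <= 0)
    stop("max_followup_years must be positive", call. = FALSE)
  if (cfg$censor_rate < 0)
    stop("censor_rate must be nonnegative", call. = FALSE)
  probs <- c(unlist(cfg$outcome_probs), cfg$missing_rates,
             cfg$contamination_rates)
  if (any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  q <- graft_cause_fractions(cfg)
  if (any(q <= 0) || any(q > 1))
    stop("implied graft-failure cause fraction outside (0, 1]; check ",
         "baseline_hazard and true_log_hr", call. = FALSE)
  for (nm in names(cfg$covariate_params)) {
    sp <- cfg$covariate_params[[nm]]
    if (!sp$kind %in% c("lognormal", "truncnorm", "categorical", "flag",
                        "zero_inflated_percent"))
      stop("unknown covariate kind for ", nm, call. = FALSE)
  }
  invisible(cfg)
}

# Group-specific probability that an all-cause event is a graft failure
# (rather than a death with functioning graft). Chosen so that the
# cause-specific graft-failure hazard ratio equals the configured
# death-censored HR exactly:
#   q_single = h_dcgf / h_allcause
#   q_dual   = q_single * HR_dcgf / HR_allcause
graft_cause_fractions <- function(cfg) {
  q_single <- cfg$baseline_hazard[["death_censored_graft"]] /
    cfg$baseline_hazard[["all_cause_graft"]]
  q_dual <- q_single * exp(cfg$true_log_hr[["death_censored_graft"]] -
                             cfg$true_log_hr[["all_cause_graft"]])
  c(dual = q_dual, single = q_single)
}
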
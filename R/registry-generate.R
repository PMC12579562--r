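#' Generate a synthetic transplant registry
#'
#' Draws `n_dual + n_single` transplant records with group-specific covariate
#' distributions, proportional-hazards survival outcomes and binomial
#' secondary outcomes, per the configuration. Output is deterministic given
#' `config$seed`, and paired configurations that differ only in effect sizes
#' reuse the same underlying uniform draws per record (common random numbers),
#' because the draw order is fixed and event times are inverse-CDF transforms
#' of pre-drawn uniforms.
#'
#' @param config a [registry_config()] object.
#' @return A `data.frame` with one row per transplant (dual rows first):
#'   identifiers, `group` ("dual"/"single"), donor / recipient / transplant
#'   covariates, observed survival times in years (`time_death`,
#'   `event_death`, `time_graftfail`, `event_graftfail` where graft failure is
#'   death-censored), and secondary outcomes (`dgf`, `los_days`,
#'   `rejection_6m`, `rejection_1y`, `creatinine_1y`; rejection and
#'   creatinine are `NA` when follow-up is too short to observe them).
#' @export
generate_registry <- function(config) {
  stopifnot(inherits(config, "registry_config"))
  validate_registry_config(config)
  n_dual <- config$n_dual
  n_single <- config$n_single
  n <- n_dual + n_single
  if (n == 0L) return(empty_registry())

  set.seed(config$seed)
  group <- rep(c("dual", "single"), c(n_dual, n_single))
  dual <- group == "dual"

  rec <- data.frame(id = sprintf("tx%07d", seq_len(n)), group = group,
                    stringsAsFactors = FALSE)
  # one latent "marginality" factor per subject; covariates are quantile
  # transforms of correlated Gaussian copula uniforms, so per-group marginals
  # are exactly the configured ones while loaded covariates co-vary
  latent <- stats::rnorm(n)
  for (nm in names(config$covariate_params)) {
    sp <- config$covariate_params[[nm]]
    lam <- if (is.null(sp$loading)) 0 else sp$loading
    z <- lam * latent + sqrt(1 - lam^2) * stats::rnorm(n)
    rec[[nm]] <- sample_covariate(sp, dual, stats::pnorm(z))
  }

  # hla_mismatch is a 0..6 integer drawn from categorical level probabilities
  if ("hla_mismatch" %in% names(rec))
    rec$hla_mismatch <- as.integer(as.character(rec$hla_mismatch))

  surv <- sample_survival(config, dual)
  rec <- cbind(rec, surv)

  # follow-up available for observing post-transplant secondary outcomes
  followup <- pmax(rec$time_death, rec$time_graftfail)
  op <- config$outcome_probs
  rec$dgf <- stats::runif(n) < ifelse(dual, op$dgf[["dual"]], op$dgf[["single"]])
  rec$rejection_6m <- ifelse(
    followup >= 0.5,
    stats::runif(n) < ifelse(dual, op$rejection_6m[["dual"]],
                             op$rejection_6m[["single"]]),
    NA)
  rec$rejection_1y <- ifelse(
    followup >= 1,
    stats::runif(n) < ifelse(dual, op$rejection_1y[["dual"]],
                             op$rejection_1y[["single"]]),
    NA)
  cr <- config$creatinine_1y
  cr_draw <- stats::rlnorm(n,
                           meanlog = ifelse(dual, log(cr$dual[["median"]]),
                                            log(cr$single[["median"]])),
                           sdlog = ifelse(dual, cr$dual[["sdlog"]],
                                          cr$single[["sdlog"]]))
  rec$creatinine_1y <- ifelse(followup >= 1, round(cr_draw, 2), NA)
  los <- config$los_days
  rec$los_days <- round(stats::rlnorm(
    n,
    meanlog = ifelse(dual, log(los$dual[["median"]]), log(los$single[["median"]])),
    sdlog = ifelse(dual, los$dual[["sdlog"]], los$single[["sdlog"]])))
  rec$los_days <- pmax(rec$los_days, 1)

  # cohort-filter fields; contamination off by default
  cr8 <- config$contamination_rates
  rec$recipient_age_lt18 <- stats::runif(n) < cr8[["age_lt18"]]
  rec$recipient_age[rec$recipient_age_lt18] <-
    round(stats::runif(sum(rec$recipient_age_lt18), 1, 17.9), 1)
  rec$living_donor <- stats::runif(n) < cr8[["living_donor"]]
  rec$en_bloc <- stats::runif(n) < cr8[["en_bloc"]]
  rec$kdri[stats::runif(n) < cr8[["missing_kdri"]]] <- NA
  drop_surv <- stats::runif(n) < cr8[["missing_survival"]]
  rec$time_death[drop_surv] <- NA
  rec$event_death[drop_surv] <- NA

  # missing-completely-at-random holes to exercise imputation
  mr <- config$missing_rates
  rec$bmi[stats::runif(n) < mr[["bmi"]]] <- NA
  rec$cit_hours[stats::runif(n) < mr[["cit_hours"]]] <- NA
  rec$los_days[stats::runif(n) < mr[["los_days"]]] <- NA

  rec
}

empty_registry <- function() {
  data.frame(id = character(0), group = character(0))
}

# Inverse-CDF sampling of one covariate from its per-group marginal, driven
# by copula uniforms u. Flags fire at HIGH u so a positive loading means
# positive association with the latent factor.
sample_covariate <- function(sp, dual, u) {
  n <- length(dual)
  switch(sp$kind,
    lognormal = {
      ml <- ifelse(dual, sp$dual[["meanlog"]], sp$single[["meanlog"]])
      sl <- ifelse(dual, sp$dual[["sdlog"]], sp$single[["sdlog"]])
      round(stats::qlnorm(u, ml, sl), 2)
    },
    truncnorm = {
      m <- ifelse(dual, sp$dual[["mean"]], sp$single[["mean"]])
      s <- ifelse(dual, sp$dual[["sd"]], sp$single[["sd"]])
      plo <- stats::pnorm((sp$lower - m) / s)
      phi <- stats::pnorm((sp$upper - m) / s)
      round(m + s * stats::qnorm(plo + u * (phi - plo)), 1)
    },
    categorical = {
      out <- character(n)
      for (g in c(TRUE, FALSE)) {
        p <- if (g) sp$dual else sp$single
        idx <- which(dual == g)
        out[idx] <- sp$levels[findInterval(u[idx], cumsum(p),
                                           rightmost.closed = TRUE) + 1L]
      }
      factor(out, levels = sp$levels)
    },
    flag = u > 1 - ifelse(dual, sp$dual, sp$single),
    zero_inflated_percent = {
      p0 <- ifelse(dual, sp$dual[["p0"]], sp$single[["p0"]])
      upos <- pmin(pmax((u - p0) / (1 - p0), 1e-12), 1 - 1e-12)
      pos <- 100 * stats::qbeta(upos,
                                ifelse(dual, sp$dual[["shape1"]], sp$single[["shape1"]]),
                                ifelse(dual, sp$dual[["shape2"]], sp$single[["shape2"]]))
      round(ifelse(u < p0, 0, pos))
    },
    stop("unknown covariate kind: ", sp$kind, call. = FALSE))
}

# Survival outcome sampling. All-cause graft failure time is exponential with
# the configured group hazard ratio; each event is attributed to graft failure
# with a group-specific cause fraction (see graft_cause_fractions) so the
# death-censored endpoint has exactly its configured hazard ratio; residual
# post-graft-loss survival is exponential. Censoring = min(uniform
# administrative, exponential loss-to-follow-up).
sample_survival <- function(config, dual) {
  n <- length(dual)
  h_ac <- config$baseline_hazard[["all_cause_graft"]]
  beta_ac <- config$true_log_hr[["all_cause_graft"]]
  q <- graft_cause_fractions(config)
  rate_ac <- h_ac * exp(ifelse(dual, beta_ac, 0))

  u_event <- stats::runif(n)
  t_ac <- -log(u_event) / rate_ac
  cause_graft <- stats::runif(n) < ifelse(dual, q[["dual"]], q[["single"]])
  t_post <- stats::rexp(n, rate = config$post_graftfail_death_hazard)
  t_death_latent <- ifelse(cause_graft, t_ac + t_post, t_ac)

  cens_admin <- stats::runif(n, 0, config$max_followup_years)
  cens_ltfu <- if (config$censor_rate > 0)
    stats::rexp(n, config$censor_rate) else rep(Inf, n)
  cens <- pmin(cens_admin, cens_ltfu)

  event_death <- t_death_latent <= cens
  time_death <- pmin(t_death_latent, cens)

  # death-censored graft failure: follow-up stops at death or censoring
  event_graftfail <- cause_graft & t_ac <= cens
  time_graftfail <- ifelse(event_graftfail, t_ac, pmin(t_ac, cens))
  # when the first event is a death with functioning graft, graft follow-up is
  # censored at that death; otherwise at administrative/loss censoring
  time_graftfail <- pmin(time_graftfail, time_death)

  data.frame(time_death = time_death, event_death = event_death,
             time_graftfail = time_graftfail, event_graftfail = event_graftfail)
}

#' Extract an endpoint's (time, event) pair from registry records
#'
#' Endpoints: `patient_survival` (death from any cause), `death_censored_graft`
#' (graft failure, censoring follow-up at death), and `all_cause_graft` (first
#' of graft failure or death).
#'
#' @param records registry data frame.
#' @param endpoint endpoint name.
#' @return data frame with columns `time` and `event`.
#' @export
endpoint_times <- function(records,
                           endpoint = c("patient_survival", "all_cause_graft",
                                        "death_censored_graft")) {
  endpoint <- match.arg(endpoint)
  out <- switch(endpoint,
    patient_survival = data.frame(time = records$time_death,
                                  event = records$event_death),
    death_censored_graft = data.frame(time = records$time_graftfail,
                                      event = records$event_graftfail),
    all_cause_graft = {
      t <- pmin(records$time_graftfail, records$time_death)
      e <- records$event_graftfail |
        (records$event_death & records$time_death <= records$time_graftfail)
      data.frame(time = t, event = e)
    })
  out$event <- as.logical(out$event)
  out
}

#' Generate a yearly waitlist transition-probability schedule
#'
#' Stand-in for the yearly registry probabilities of being transplanted, dying
#' on the waitlist, and of a transplant being performed as a dual, over an
#' 11-year horizon. Optional multiplicative log-normal jitter gives mild
#' year-to-year variation; with `jitter_sd = 0` the schedule is constant at
#' the base values.
#'
#' @param seed integer seed.
#' @param base_p_transplant annual probability of transplant from the list.
#' @param base_p_death annual probability of death on the list.
#' @param dual_fraction fraction of transplants performed as duals.
#' @param n_years schedule length (default 11).
#' @param jitter_sd log-scale jitter SD (default 0.05; 0 disables).
#' @param start_year first calendar year label.
#' @return A `data.frame` of class `waitlist_schedule` with columns `year`,
#'   `p_transplant`, `p_death`, `dual_fraction`.
#' @export
generate_waitlist_schedule <- function(seed = 1L, base_p_transplant = 0.14,
                                       base_p_death = 0.05,
                                       dual_fraction = 0.01, n_years = 11L,
                                       jitter_sd = 0.05, start_year = 2014L) {
  if (base_p_transplant < 0 || base_p_death < 0 ||
      base_p_transplant + base_p_death > 1)
    stop("base_p_transplant + base_p_death must lie in [0, 1]", call. = FALSE)
  if (dual_fraction < 0 || dual_fraction > 1)
    stop("dual_fraction must lie in [0, 1]", call. = FALSE)
  if (n_years < 1) stop("n_years must be positive", call. = FALSE)
  set.seed(seed)
  jit <- function(x) {
    if (jitter_sd <= 0) return(rep(x, n_years))
    x * exp(stats::rnorm(n_years, 0, jitter_sd))
  }
  sched <- data.frame(year = seq(start_year, length.out = n_years),
                      p_transplant = jit(base_p_transplant),
                      p_death = jit(base_p_death),
                      dual_fraction = pmin(jit(dual_fraction), 1))
  # keep each year a valid sub-probability pair after jitter
  over <- sched$p_transplant + sched$p_death > 1
  if (any(over)) {
    tot <- sched$p_transplant[over] + sched$p_death[over]
    sched$p_transplant[over] <- sched$p_transplant[over] / tot
    sched$p_death[over] <- sched$p_death[over] / tot
  }
  class(sched) <- c("waitlist_schedule", "data.frame")
  sched
}

#' Validate a waitlist schedule
#' @param schedule a `waitlist_schedule` or compatible data frame.
#' @return the schedule, invisibly; errors if invalid.
#' @export
validate_waitlist_schedule <- function(schedule) {
  need <- c("year", "p_transplant", "p_death", "dual_fraction")
  if (!all(need %in% names(schedule)))
    stop("schedule must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  with(schedule, {
    if (any(p_transplant < 0) || any(p_death < 0) ||
        any(p_transplant + p_death > 1 + 1e-12))
      stop("each year must satisfy p_transplant + p_death <= 1", call. = FALSE)
    if (any(dual_fraction < 0) || any(dual_fraction > 1))
      stop("dual_fraction must lie in [0, 1]", call. = FALSE)
  })
  invisible(schedule)
}
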
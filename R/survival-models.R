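#' Endpoint specifications
#'
#' The three study endpoints: patient survival (death from any cause),
#' all-cause graft survival (graft failure or death, whichever first), and
#' death-censored graft survival (graft failure; death with a functioning
#' graft censors follow-up without counting as an event).
#'
#' @param name endpoint name.
#' @return list with `name`, and a description of the censoring rule.
#' @export
endpoint_spec <- function(name = c("patient_survival", "all_cause_graft",
                                   "death_censored_graft")) {
  name <- match.arg(name)
  rule <- switch(name,
    patient_survival = "death from any cause; censored at last follow-up",
    all_cause_graft = "graft failure or death, whichever occurs first",
    death_censored_graft = paste("graft failure only; death with a",
                                 "functioning graft censors follow-up"))
  list(name = name, censoring_rule = rule)
}

#' Kaplan-Meier product-limit estimator
#'
#' @param times follow-up times (years, >= 0).
#' @param events event indicators (TRUE/1 = event, FALSE/0 = censored).
#' @param group optional group label attached to the fit.
#' @return An object of class `survival_fit`: `times` (ordered event times),
#'   `survival`, `at_risk`, `n_event`, `std_err` (Greenwood standard error of
#'   the survival estimate), `group`, and the underlying `survfit` object.
#' @export
kaplan_meier <- function(times, events, group = NULL) {
  if (length(times) == 0) stop("no observations", call. = FALSE)
  if (any(times < 0)) stop("times must be nonnegative", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                           conf.type = "log")
  structure(list(times = fit$time, survival = fit$surv,
                 at_risk = fit$n.risk, n_event = fit$n.event,
                 std_err = fit$surv * fit$std.err,
                 group = group, survfit = fit),
            class = "survival_fit")
}

#' Evaluate a Kaplan-Meier fit at arbitrary times
#'
#' Right-continuous step interpolation of the product-limit estimate.
#'
#' @param fit a `survival_fit`.
#' @param t query times.
#' @return survival probabilities at `t`.
#' @export
km_survival_at <- function(fit, t) {
  idx <- findInterval(t, fit$times)
  ifelse(idx == 0, 1, fit$survival[pmax(idx, 1)])
}

#' Two-group log-rank test
#'
#' Standard two-sample log-rank chi-square statistic on one degree of
#' freedom. Identical groups give statistic 0 and p = 1; with no events in
#' either group the result is flagged degenerate.
#'
#' @param times,events follow-up data for all subjects.
#' @param group two-level group vector.
#' @return list with `statistic`, `p_value`, `degenerate`.
#' @export
log_rank_test <- function(times, events, group) {
  group <- factor(group)
  if (nlevels(group) != 2 || any(table(group) == 0))
    stop("log-rank test requires two nonempty groups", call. = FALSE)
  if (sum(events) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, degenerate = TRUE))
  sd <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ group)
  stat <- unname(sd$chisq)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood with the Efron approximation for tied
#' event times (Newton-Raphson); returns hazard ratios with Wald 95%
#' confidence intervals and p-values. With `covariates = "group"` this is the
#' univariable dual-vs-single model; the multivariable model adds the
#' adjustment covariates.
#'
#' @param records registry data frame (must contain `group` when it is among
#'   the covariates).
#' @param endpoint endpoint name (see [endpoint_spec()]).
#' @param covariates character vector of model terms (default "group").
#' @return An object of class `cox_fit`: `coefficients`, `hazard_ratios`,
#'   `se`, `ci95` (matrix with columns low/high), `p_values`,
#'   `ties_method` ("efron"), `log_partial_likelihood`, `n_events`, plus the
#'   underlying `coxph` fit.
#' @export
cox_fit <- function(records, endpoint = "death_censored_graft",
                    covariates = "group") {
  te <- endpoint_times(records, endpoint)
  if (sum(te$event) < 1) stop("no events for endpoint ", endpoint, call. = FALSE)
  dat <- records[, intersect(covariates, names(records)), drop = FALSE]
  if ("group" %in% names(dat))
    dat$group <- factor(dat$group, levels = c("single", "dual"))
  dat$.time <- te$time
  dat$.event <- as.integer(te$event)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = dat, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite", conditionMessage(w)))
        stop("monotone partial likelihood: a coefficient diverges (no events ",
             "in one group level?)", call. = FALSE)
      suppressWarnings(
        survival::coxph(fml, data = dat, ties = "efron",
                        control = survival::coxph.control(eps = 1e-9,
                                                          iter.max = 50)))
    })
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("singular information matrix in Cox fit", call. = FALSE)
  if (any(abs(cf) > 15))
    stop("monotone partial likelihood: a coefficient diverges", call. = FALSE)
  se <- stats::setNames(sqrt(diag(fit$var)), names(cf))
  ci <- cbind(low = exp(cf - 1.96 * se), high = exp(cf + 1.96 * se))
  structure(list(coefficients = cf, hazard_ratios = exp(cf), se = se,
                 ci95 = ci,
                 p_values = 2 * stats::pnorm(-abs(cf / se)),
                 ties_method = "efron",
                 log_partial_likelihood = fit$loglik[2],
                 n_events = fit$nevent, coxph = fit, endpoint = endpoint),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox PH fit (", x$endpoint, ", Efron ties, ", x$n_events, " events)\n",
      sep = "")
  tab <- data.frame(term = names(x$coefficients),
                    HR = round(x$hazard_ratios, 3),
                    ci_low = round(x$ci95[, "low"], 3),
                    ci_high = round(x$ci95[, "high"], 3),
                    p = signif(x$p_values, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Survival table at query years, by group
#'
#' Reproduces the per-endpoint reporting layout: survival percent and number
#' at risk at the query years for each group, an overall log-rank p-value,
#' and a pointwise per-year comparison p-value from the normal approximation
#' on the difference of the two Kaplan-Meier estimates with Greenwood
#' standard errors (the published tables do not state their per-year test;
#' this pointwise test is the documented choice here).
#'
#' @param records registry data frame.
#' @param endpoint endpoint name.
#' @param query_years years at which to report (default 1, 2, 4, 6).
#' @return list with `table` (year, dual %, dual at-risk, single %, single
#'   at-risk, pointwise p) and `log_rank_p` (overall comparison).
#' @export
survival_table <- function(records, endpoint = "patient_survival",
                           query_years = c(1, 2, 4, 6)) {
  te <- endpoint_times(records, endpoint)
  dual <- records$group == "dual"
  fit_d <- kaplan_meier(te$time[dual], te$event[dual], group = "dual")
  fit_s <- kaplan_meier(te$time[!dual], te$event[!dual], group = "single")
  lr <- log_rank_test(te$time, te$event, records$group)
  max_t <- c(max(te$time[dual]), max(te$time[!dual]))

  at_risk <- function(fit, times, t) {
    vapply(t, function(tt) sum(times >= tt), numeric(1))
  }
  se_at <- function(fit, t) {
    idx <- findInterval(t, fit$times)
    ifelse(idx == 0, 0, fit$std_err[pmax(idx, 1)])
  }
  s_d <- km_survival_at(fit_d, query_years)
  s_s <- km_survival_at(fit_s, query_years)
  z <- (s_d - s_s) / sqrt(se_at(fit_d, query_years)^2 +
                            se_at(fit_s, query_years)^2)
  p_point <- 2 * stats::pnorm(-abs(z))
  tab <- data.frame(year = query_years,
                    dual_percent = round(100 * s_d, 1),
                    dual_at_risk = at_risk(fit_d, te$time[dual], query_years),
                    single_percent = round(100 * s_s, 1),
                    single_at_risk = at_risk(fit_s, te$time[!dual], query_years),
                    p_value = p_point,
                    estimable = query_years <= min(max_t))
  list(table = tab, log_rank_p = lr$p_value, fits = list(dual = fit_d,
                                                         single = fit_s))
}

#' Cox hazard-ratio summary table across the three endpoints
#'
#' Univariable (group only) and multivariable (group plus the adjustment
#' covariates used in the study: donor preservation, KDRI, donor sex, CIT,
#' glomerulosclerosis, inotropic support, EPTS, dialysis vintage group, PVD,
#' renal diagnosis, BMI, cPRA, ABO incompatibility, HLA mismatch, induction)
#' dual-vs-single hazard ratios per endpoint.
#'
#' @param records matched registry data frame.
#' @param adjustment covariates for the multivariable model.
#' @return data frame: endpoint, model, HR, ci_low, ci_high, p.
#' @export
cox_summary_table <- function(records,
                              adjustment = c("pump", "kdri", "donor_female",
                                             "cit_hours", "glomerulosclerosis",
                                             "inotropic_support", "epts",
                                             "dialysis_group", "pvd",
                                             "renal_diagnosis", "bmi", "cpra",
                                             "abo_incompatible", "hla_mismatch",
                                             "induction")) {
  adjustment <- intersect(adjustment, names(records))
  rows <- list()
  for (ep in c("patient_survival", "all_cause_graft", "death_censored_graft")) {
    for (model in c("univariable", "multivariable")) {
      covs <- if (model == "univariable") "group" else c("group", adjustment)
      fit <- cox_fit(records, ep, covs)
      i <- grep("^group", names(fit$coefficients))
      rows[[paste(ep, model)]] <- data.frame(
        endpoint = ep, model = model,
        hr = unname(fit$hazard_ratios[i]),
        ci_low = unname(fit$ci95[i, "low"]),
        ci_high = unname(fit$ci95[i, "high"]),
        p = unname(fit$p_values[i]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
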
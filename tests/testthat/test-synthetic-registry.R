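test_that("generation is deterministic given the seed", {
  cfg <- registry_config(n_dual = 150, n_single = 400, seed = 7)
  r1 <- generate_registry(cfg)
  r2 <- generate_registry(cfg)
  expect_identical(r1, r2)
  r3 <- generate_registry(registry_config(n_dual = 150, n_single = 400, seed = 8))
  expect_false(identical(r1, r3))
})

test_that("record invariants hold across seeds", {
  for (s in 1:5) {
    cfg <- registry_config(n_dual = 120, n_single = 300, seed = s)
    rec <- generate_registry(cfg)
    expect_equal(nrow(rec), 420)
    expect_true(all(rec$time_death >= 0))
    expect_true(all(rec$time_graftfail >= 0))
    expect_true(all(rec$time_graftfail <= rec$time_death + 1e-12))
    expect_true(all(rec$time_death[rec$event_death] <=
                      cfg$max_followup_years))
    expect_true(all(rec$time_graftfail[rec$event_graftfail] <=
                      cfg$max_followup_years))
    expect_true(all(rec$kdri > 0, na.rm = TRUE))
    expect_true(all(rec$hla_mismatch %in% 0:6))
    # a death-censored graft failure never happens after the observed death
    gf <- rec$event_graftfail
    expect_true(all(rec$time_graftfail[gf] <= rec$time_death[gf] + 1e-12))
  }
})

test_that("covariate marginals converge to configured values at large n", {
  n <- 1e5
  rec <- generate_registry(registry_config(n_dual = n, n_single = 0, seed = 11))
  prm <- default_covariate_params()

  # log-normal medians are exact model medians; median SE ~ 1.2533 sd/sqrt(n)
  med_se <- function(x) {
    x <- x[!is.na(x)]
    1.2533 * stats::sd(x) / sqrt(length(x))
  }
  expect_lt(abs(median(rec$kdri) - 1.88), 3 * med_se(rec$kdri) + 0.005)
  expect_lt(abs(median(rec$bmi, na.rm = TRUE) - 27.4),
            3 * med_se(rec$bmi) + 0.005)

  # truncated-normal median from the inverse-CDF form used independently here
  tn_median <- function(m, s, lo, hi)
    m + s * qnorm((pnorm((lo - m) / s) + pnorm((hi - m) / s)) / 2)
  exp_med <- tn_median(prm$donor_age$dual[["mean"]],
                       prm$donor_age$dual[["sd"]], 5, 90)
  expect_lt(abs(median(rec$donor_age) - exp_med),
            3 * med_se(rec$donor_age) + 0.05)

  # categorical level proportions within 3 binomial SEs
  p_cfg <- prm$dialysis_group$dual
  p_obs <- as.numeric(table(rec$dialysis_group) / n)
  se <- sqrt(p_cfg * (1 - p_cfg) / n)
  expect_true(all(abs(p_obs - p_cfg) <= 3 * se + 1e-6))

  # flags
  expect_lt(abs(mean(rec$pump) - 736 / 1015), 3 * sqrt(0.2 / n) + 1e-6)
})

test_that("secondary outcome rates match configured group proportions", {
  rec <- generate_registry(registry_config(n_dual = 1015, n_single = 3045,
                                           seed = 21))
  p_d <- mean(rec$dgf[rec$group == "dual"])
  p_s <- mean(rec$dgf[rec$group == "single"])
  expect_lt(abs(p_d - 0.393), 3 * sqrt(0.393 * 0.607 / 1015))
  expect_lt(abs(p_s - 0.317), 3 * sqrt(0.317 * 0.683 / 3045))
})

test_that("single-group survival follows the configured exponential hazard", {
  # near-uncensored configuration: long administrative window, no dropout
  cfg <- registry_config(n_dual = 0, n_single = 20000, seed = 5,
                         censor_rate = 0, max_followup_years = 500)
  rec <- generate_registry(cfg)
  te <- endpoint_times(rec, "all_cause_graft")
  fit <- kaplan_meier(te$time, te$event)
  h0 <- cfg$baseline_hazard[["all_cause_graft"]]
  for (t in c(1, 3, 6)) {
    s_hat <- km_survival_at(fit, t)
    s_true <- exp(-h0 * t)
    expect_lt(abs(s_hat - s_true), 3 * sqrt(s_true * (1 - s_true) / 20000))
  }
})

test_that("configured hazard ratios are recovered by downstream Cox fits", {
  # null effect at large n
  cfg <- registry_config(n_dual = 4000, n_single = 4000, seed = 3,
                         true_log_hr = c(all_cause_graft = 0,
                                         death_censored_graft = 0))
  rec <- generate_registry(cfg)
  fit <- cox_fit(rec, "death_censored_graft")
  expect_lt(abs(fit$coefficients[["groupdual"]]), 3 * fit$se[["groupdual"]])
  fit_ac <- cox_fit(rec, "all_cause_graft")
  expect_lt(abs(fit_ac$coefficients[["groupdual"]]),
            3 * fit_ac$se[["groupdual"]])
})

test_that("invalid generator configurations are rejected", {
  expect_error(registry_config(baseline_hazard = c(all_cause_graft = -1,
                                                   death_censored_graft = 0.04)),
               "positive")
  expect_error(registry_config(max_followup_years = 0), "positive")
  expect_error(registry_config(missing_rates = c(bmi = 1.2, cit_hours = 0,
                                                 los_days = 0)),
               "probabilit")
  expect_error(cov_categorical(c("a", "b"), c(0.6, 0.6), c(0.5, 0.5)),
               "sum to 1")
})

test_that("waitlist schedule generator honours its contract", {
  sch <- generate_waitlist_schedule(seed = 2, base_p_transplant = 0.15,
                                    base_p_death = 0.05, dual_fraction = 0.01,
                                    n_years = 11)
  expect_equal(nrow(sch), 11)
  expect_true(all(sch$p_transplant + sch$p_death <= 1))
  expect_true(all(sch$dual_fraction >= 0 & sch$dual_fraction <= 1))
  # deterministic given seed
  expect_identical(sch, generate_waitlist_schedule(seed = 2,
                                                   base_p_transplant = 0.15,
                                                   base_p_death = 0.05,
                                                   dual_fraction = 0.01,
                                                   n_years = 11))
  # jitter disabled -> constant at the base values
  flat <- generate_waitlist_schedule(seed = 9, base_p_transplant = 0.12,
                                     base_p_death = 0.04,
                                     dual_fraction = 0.02, n_years = 5,
                                     jitter_sd = 0)
  expect_equal(flat$p_transplant, rep(0.12, 5))
  expect_equal(flat$p_death, rep(0.04, 5))
  expect_equal(flat$dual_fraction, rep(0.02, 5))
  expect_error(generate_waitlist_schedule(base_p_transplant = 0.8,
                                          base_p_death = 0.3),
               "must lie in")
})
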
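test_that("Kaplan-Meier matches the hand product-limit on the 3-subject toy", {
  d <- toy_km_data()
  fit <- kaplan_meier(d$times, d$events)
  # events at 1 (3 at risk) and 3 (1 at risk); censored at 2
  expect_equal(km_survival_at(fit, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(km_survival_at(fit, 2.5), 2 / 3, tolerance = 1e-12)  # step fn
  expect_equal(km_survival_at(fit, 3), 0, tolerance = 1e-12)
  expect_equal(km_survival_at(fit, 0.5), 1)
  expect_error(kaplan_meier(numeric(0), logical(0)), "no observations")
})

test_that("with no events the survival curve stays at 1", {
  fit <- kaplan_meier(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_true(all(fit$survival == 1))
  expect_equal(km_survival_at(fit, 2.9), 1)
})

test_that("KM equals one minus the empirical CDF without censoring", {
  set.seed(3)
  t <- rexp(400, 0.3)
  fit <- kaplan_meier(t, rep(TRUE, 400))
  for (q in c(0.5, 1, 2, 5))
    expect_equal(km_survival_at(fit, q), mean(t > q), tolerance = 1e-12)
})

test_that("log-rank: identical groups give statistic 0, p 1", {
  t <- c(1, 2, 3, 4); e <- c(TRUE, TRUE, FALSE, TRUE)
  lr <- log_rank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)
})

test_that("log-rank matches the hand (O-E)^2/V computation on a toy", {
  # 3 subjects per group; events at distinct times 1 (A), 2 (B), 5 (A);
  # censoring at 3 (A), 4 (B), 6 (B)
  time <- c(1, 5, 3, 2, 6, 4)
  event <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  group <- c("A", "A", "A", "B", "B", "B")
  # hand computation of the group-A log-rank statistic
  O <- 0; E <- 0; V <- 0
  for (tt in sort(time[event])) {
    at_risk <- time >= tt
    n <- sum(at_risk); nA <- sum(at_risk & group == "A")
    d <- sum(event & time == tt); dA <- sum(event & time == tt & group == "A")
    O <- O + dA
    E <- E + d * nA / n
    if (n > 1) V <- V + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
  }
  expect_gt(V, 0)
  lr <- log_rank_test(time, event, group)
  expect_equal(lr$statistic, (O - E)^2 / V, tolerance = 1e-9)
})

test_that("log-rank equals the Cox score test for a binary covariate, no ties", {
  set.seed(6)
  n <- 60
  g <- rep(c("dual", "single"), each = n / 2)
  t <- rexp(n, ifelse(g == "dual", 0.3, 0.5))
  e <- runif(n) < 0.8
  stopifnot(!anyDuplicated(t[e]))
  lr <- log_rank_test(t, e, g)
  cph <- survival::coxph(survival::Surv(t, e) ~ g)
  expect_equal(lr$statistic, unname(summary(cph)$sctest["test"]),
               tolerance = 1e-6)
})

test_that("Cox coefficient matches brute-force partial-likelihood maximization", {
  set.seed(11)
  n <- 20
  rec <- data.frame(
    id = sprintf("s%02d", 1:n),
    group = rep(c("dual", "single"), each = n / 2))
  x <- as.integer(rec$group == "dual")
  t <- round(rexp(n, ifelse(x == 1, 0.2, 0.4)), 6)
  stopifnot(!anyDuplicated(t))
  rec$time_graftfail <- t
  rec$event_graftfail <- rep(TRUE, n)
  rec$time_death <- t
  rec$event_death <- rep(FALSE, n)
  fit <- cox_fit(rec, "death_censored_graft")
  # independent oracle: maximize the written partial likelihood numerically
  opt <- stats::optimize(function(b) cox_partial_loglik(b, t, rep(TRUE, n), x),
                         interval = c(-5, 5), maximum = TRUE, tol = 1e-9)
  expect_equal(unname(fit$coefficients["groupdual"]), opt$maximum,
               tolerance = 1e-4)
  # the written log-likelihood is flat at the returned coefficient
  b <- unname(fit$coefficients["groupdual"])
  h <- 1e-5
  grad <- (cox_partial_loglik(b + h, t, rep(TRUE, n), x) -
             cox_partial_loglik(b - h, t, rep(TRUE, n), x)) / (2 * h)
  expect_lt(abs(grad), 1e-4)
  # Wald interval is reproduced from coef and se
  expect_equal(unname(fit$ci95[, "low"]),
               unname(exp(fit$coefficients - 1.96 * fit$se)), tolerance = 1e-6)
  expect_equal(unname(fit$ci95[, "high"]),
               unname(exp(fit$coefficients + 1.96 * fit$se)), tolerance = 1e-6)
})

test_that("a monotone partial likelihood raises an error", {
  rec <- data.frame(id = c("a", "b"), group = c("dual", "single"),
                    time_graftfail = c(1, 2), event_graftfail = c(TRUE, TRUE),
                    time_death = c(1, 2), event_death = c(FALSE, FALSE))
  expect_error(cox_fit(rec, "death_censored_graft"), "monotone|diverges")
})

test_that("endpoint extraction applies the censoring rules", {
  rec <- data.frame(
    id = c("a", "b", "c"),
    group = c("dual", "single", "single"),
    # a: graft failure at 1, death at 2; b: death with functioning graft at 3;
    # c: censored at 4
    time_graftfail = c(1, 3, 4), event_graftfail = c(TRUE, FALSE, FALSE),
    time_death = c(2, 3, 4), event_death = c(TRUE, TRUE, FALSE))
  dc <- endpoint_times(rec, "death_censored_graft")
  expect_equal(dc$time, c(1, 3, 4))
  expect_equal(dc$event, c(TRUE, FALSE, FALSE))
  ac <- endpoint_times(rec, "all_cause_graft")
  expect_equal(ac$time, c(1, 3, 4))
  expect_equal(ac$event, c(TRUE, TRUE, FALSE))
  ps <- endpoint_times(rec, "patient_survival")
  expect_equal(ps$event, c(TRUE, TRUE, FALSE))
})

test_that("survival tables report stepwise estimates, at-risk counts and p-values", {
  rec <- data.frame(
    id = sprintf("s%02d", 1:6),
    group = rep(c("dual", "single"), each = 3),
    time_graftfail = c(1, 2, 3, 1, 2, 3),
    event_graftfail = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
    time_death = c(1, 2, 3, 1, 2, 3),
    event_death = rep(FALSE, 6))
  st <- survival_table(rec, "death_censored_graft", query_years = c(0, 2.5, 10))
  expect_equal(st$table$dual_percent[1], 100)
  expect_equal(st$table$single_percent[1], 100)
  expect_equal(st$table$dual_percent[2], 66.7)  # reported to one decimal
  expect_false(st$table$estimable[3])
  expect_true(st$table$estimable[2])
  # identical groups -> overall log-rank p of 1
  expect_equal(st$log_rank_p, 1, tolerance = 1e-9)
})

test_that("Cox summary table covers the three endpoints in both models", {
  rec <- small_registry(23, n_dual = 300, n_single = 900)
  tab <- cox_summary_table(rec, adjustment = c("kdri", "epts"))
  expect_equal(nrow(tab), 6)
  expect_setequal(unique(tab$endpoint),
                  c("patient_survival", "all_cause_graft",
                    "death_censored_graft"))
  expect_true(all(tab$ci_low <= tab$hr & tab$hr <= tab$ci_high))
})
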
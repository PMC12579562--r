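test_that("logistic fit on a 2x2 table reproduces the closed-form log odds ratio", {
  # dual: 10 exposed / 20 unexposed; single: 30 exposed / 120 unexposed
  rec <- data.frame(
    group = rep(c("dual", "single"), c(30, 150)),
    exposed = c(rep(c(TRUE, FALSE), c(10, 20)), rep(c(TRUE, FALSE), c(30, 120))))
  m <- fit_propensity(rec, "exposed")
  expect_equal(unname(m$coefficients["exposedTRUE"]),
               log((10 * 120) / (20 * 30)), tolerance = 1e-8)
  expect_true(m$converged)
})

test_that("a covariate identical across groups yields a null model", {
  set.seed(4)
  rec <- data.frame(group = rep(c("dual", "single"), c(500, 1500)),
                    x = rnorm(2000))
  m <- fit_propensity(rec, "x")
  expect_lt(abs(unname(m$coefficients["x"])), 0.2)
  expect_lt(max(abs(m$scores - 0.25)), 0.1)
})

test_that("the score equations are satisfied at the optimum", {
  rec <- small_registry(17)
  m <- fit_propensity(rec, c("donor_age", "kdri", "pump"))
  X <- stats::model.matrix(m$fit)
  y <- as.integer(rec$group == "dual")
  grad <- drop(t(X) %*% (y - m$scores))
  expect_lt(max(abs(grad)), 1e-6)
})

test_that("perfect separation and collinearity raise informative errors", {
  rec <- data.frame(group = rep(c("dual", "single"), each = 20),
                    x = c(rnorm(20, 10), rnorm(20, -10)))
  expect_error(suppressWarnings(fit_propensity(rec, "x")), "separation")
  rec2 <- data.frame(group = rep(c("dual", "single"), each = 20),
                     a = rnorm(40))
  rec2$b <- 2 * rec2$a
  expect_error(fit_propensity(rec2, c("a", "b")), "rank|aliased")
})

test_that("nearest-neighbor matching picks the closest unused controls", {
  # distances are measured on the logit of the score: t1 = 0.8 is nearer to
  # c2 = 0.79 (|logit diff| 0.061) than to c1 = 0.81 (0.064)
  scores <- c(t1 = 0.8, t2 = 0.2,
              c1 = 0.81, c2 = 0.79, c3 = 0.5, c4 = 0.22, c5 = 0.19, c6 = 0.05)
  mc <- nearest_neighbor_match(scores, c("t1", "t2"), paste0("c", 1:6),
                               ratio = 1, seed = 1)
  pairs <- setNames(mc$pairs$control_id, mc$pairs$treated_id)
  expect_equal(unname(pairs["t1"]), "c2")
  expect_equal(unname(pairs["t2"]), "c5")
  # and the same instance agrees with the exhaustive oracle
  orc <- oracle_greedy_match(qlogis(scores[1:2]), qlogis(scores[3:8]), 1)
  expect_setequal(paste(mc$pairs$treated_id, mc$pairs$control_id),
                  paste(paste0("t", orc[, "treated"]),
                        paste0("c", orc[, "control"])))
})

test_that("greedy matching equals the brute-force oracle on small instances", {
  set.seed(99)
  for (rep in 1:40) {
    n_t <- sample(1:4, 1)
    ratio <- sample(1:3, 1)
    if (ratio * n_t > 12 - n_t) next
    lo <- ratio * n_t; hi <- 12 - n_t
    n_c <- lo + sample.int(hi - lo + 1, 1) - 1
    lt <- round(rnorm(n_t), sample(c(1, 2, 8), 1))  # coarse rounding forces ties
    lc <- round(rnorm(n_c), sample(c(1, 2, 8), 1))
    # distinct scores so the processing order is unambiguous
    if (anyDuplicated(lt)) next
    scores <- plogis(c(lt, lc))
    names(scores) <- c(paste0("t", seq_len(n_t)), paste0("c", seq_len(n_c)))
    mc <- nearest_neighbor_match(scores, paste0("t", seq_len(n_t)),
                                 paste0("c", seq_len(n_c)),
                                 ratio = ratio, seed = rep)
    # oracle works on the same logit scale
    orc <- oracle_greedy_match(qlogis(scores[seq_len(n_t)]),
                               qlogis(scores[n_t + seq_len(n_c)]), ratio)
    got <- paste(mc$pairs$treated_id, mc$pairs$control_id)
    want <- paste(paste0("t", orc[, "treated"]), paste0("c", orc[, "control"]))
    # control-score ties make specific ids ambiguous; compare matched
    # distance multisets, and exact pairs when scores are distinct
    d_got <- sort(abs(qlogis(scores[mc$pairs$treated_id]) -
                        qlogis(scores[mc$pairs$control_id])))
    d_want <- sort(abs(lt[orc[, "treated"]] - lc[orc[, "control"]]))
    expect_equal(unname(d_got), unname(d_want), tolerance = 1e-10)
    if (!anyDuplicated(lc)) expect_setequal(got, want)
  }
})

test_that("matching is without replacement and deterministic under ties", {
  scores <- c(setNames(rep(0.5, 4), paste0("t", 1:4)),
              setNames(rep(0.5, 12), paste0("c", 1:12)))
  m1 <- nearest_neighbor_match(scores, paste0("t", 1:4), paste0("c", 1:12),
                               ratio = 3, seed = 42)
  m2 <- nearest_neighbor_match(scores, paste0("t", 1:4), paste0("c", 1:12),
                               ratio = 3, seed = 42)
  expect_identical(m1$pairs, m2$pairs)
  expect_equal(anyDuplicated(m1$pairs$control_id), 0L)
  expect_equal(nrow(m1$pairs), 12)
})

test_that("a control shortfall errors under the strict policy", {
  scores <- c(t1 = 0.6, t2 = 0.4, c1 = 0.5)
  expect_error(nearest_neighbor_match(scores, c("t1", "t2"), "c1", ratio = 1),
               "not enough controls")
})

test_that("standardized mean differences follow the stated formulas", {
  expect_equal(standardized_mean_difference(c(1, 2, 3), c(1, 2, 3)), 0)
  # means 1 vs 0, both variances 1
  a <- c(0, 1, 2); b <- c(-1, 0, 1)
  expect_equal(standardized_mean_difference(a, b), 1.0)
  # proportions 0.30 vs 0.20 -> 0.1 / sqrt(0.185)
  pa <- rep(c(TRUE, FALSE), c(30, 70)); pb <- rep(c(TRUE, FALSE), c(20, 80))
  expect_equal(standardized_mean_difference(pa, pb, type = "binary"),
               0.1 / sqrt((0.3 * 0.7 + 0.2 * 0.8) / 2), tolerance = 1e-10)
  # zero pooled variance with unequal means -> infinite flag
  expect_equal(standardized_mean_difference(c(1, 1), c(0, 0)), Inf)
  # categorical: maximum absolute per-level SMD
  fa <- factor(rep(c("x", "y"), c(8, 2)))
  fb <- factor(rep(c("x", "y"), c(2, 8)))
  expect_equal(abs(standardized_mean_difference(fa, fb)),
               abs(standardized_mean_difference(fa == "x", fb == "x",
                                                type = "binary")))
})

test_that("ratio selection returns the largest balanced ratio", {
  # randomized groups: everything balances, so the largest ratio wins
  set.seed(8)
  n <- 1200
  rec <- data.frame(id = sprintf("r%04d", 1:n),
                    group = rep(c("dual", "single"), c(150, n - 150)),
                    x = rnorm(n), z = rnorm(n))
  sel <- select_matching_ratio(rec, c("x", "z"), ratios = c(1, 2, 3),
                               threshold = 0.1, seed = 1)
  expect_equal(sel$ratio, 3L)
  expect_true(sel$balanced)
  expect_true(all(abs(sel$balance$smd_after) <= 0.1))
  expect_equal(nrow(sel$candidates), 3)
})

test_that("an unbalanceable covariate sets the not-balanced flag", {
  # disjoint supports: no control resembles any treated unit
  set.seed(12)
  n_t <- 60; n_c <- 300
  rec <- data.frame(id = sprintf("r%04d", 1:(n_t + n_c)),
                    group = rep(c("dual", "single"), c(n_t, n_c)),
                    x = c(rnorm(n_t, 6, 0.5), rnorm(n_c, 0, 0.5)))
  sel <- tryCatch(
    suppressWarnings(select_matching_ratio(rec, "x", ratios = c(1, 2),
                                           threshold = 0.1, seed = 1)),
    error = function(e) e)
  if (inherits(sel, "error")) {
    # complete separation of the propensity model is an acceptable outcome
    expect_match(conditionMessage(sel), "separation")
  } else {
    expect_false(sel$balanced)
    expect_gt(sel$max_abs_smd, 0.1)
  }
})

test_that("matching reduces confounding on average over seeds", {
  deltas <- sapply(1:20, function(s) {
    rec <- small_registry(s, n_dual = 120, n_single = 1500)
    m <- fit_propensity(rec, c("donor_age", "kdri", "epts"))
    sc <- setNames(m$scores, rec$id)
    mc <- nearest_neighbor_match(sc, rec$id[rec$group == "dual"],
                                 rec$id[rec$group == "single"],
                                 ratio = 1, seed = s)
    bal <- match_balance(rec, mc, c("donor_age", "kdri", "epts"))
    mean(abs(bal$smd_before)) - mean(abs(bal$smd_after))
  })
  expect_gt(mean(deltas), 0)
})
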
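# Hand-built toy registries for filter/imputation/survival tests.

toy_filter_records <- function() {
  n <- 10
  data.frame(
    id = sprintf("r%02d", 1:n),
    group = rep(c("dual", "single"), each = 5),
    recipient_age = c(17, 16, 45, 50, 55, 60, 65, 70, 40, 35),
    living_donor = c(FALSE, FALSE, TRUE, FALSE, FALSE,
                     FALSE, FALSE, FALSE, FALSE, FALSE),
    en_bloc = c(FALSE, FALSE, FALSE, TRUE, FALSE,
                FALSE, FALSE, FALSE, FALSE, FALSE),
    kdri = rep(1.2, n),
    time_death = rep(2, n), event_death = rep(FALSE, n),
    time_graftfail = rep(2, n), event_graftfail = rep(FALSE, n),
    stringsAsFactors = FALSE
  )
}

toy_impute_records <- function() {
  data.frame(
    id = sprintf("r%02d", 1:6),
    group = rep(c("dual", "single"), 3),
    recipient_age = c(30, 40, 50, 60, 70, 20),
    recipient_female = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    race = factor(c("white", "black", "white", "black", "white", "black")),
    bmi = 20 + 0.1 * c(30, 40, NA, 60, 70, 20),
    sharing = factor(rep(c("local", "national"), 3)),
    distance_miles = c(10, 300, 20, 250, 15, 280),
    cit_hours = 5 + 0.02 * c(10, 300, 20, 250, 15, 280),
    los_days = c(3, 5, 9, NA, 5, 3),
    stringsAsFactors = FALSE
  )
}

# tiny registry for survival toys: 3 subjects, times {1, 2 (censored), 3}
toy_km_data <- function() list(times = c(1, 2, 3), events = c(TRUE, FALSE, TRUE))

# small registry generator config for fast stochastic tests
small_registry <- function(seed, n_dual = 200, n_single = 600) {
  generate_registry(registry_config(n_dual = n_dual, n_single = n_single,
                                    seed = seed))
}

# naive transliteration of the greedy matching rule, used as the oracle:
# process treated in descending score order (given explicitly), and for each,
# repeatedly scan every control for the nearest unused one.
oracle_greedy_match <- function(lt, lc, ratio) {
  used <- rep(FALSE, length(lc))
  res <- list()
  for (i in order(-lt)) {
    for (k in seq_len(ratio)) {
      best <- NA; bestd <- Inf
      for (j in seq_along(lc)) {
        if (!used[j] && abs(lc[j] - lt[i]) < bestd) {
          best <- j; bestd <- abs(lc[j] - lt[i])
        }
      }
      if (is.na(best)) stop("oracle exhausted")
      used[best] <- TRUE
      res[[length(res) + 1]] <- c(treated = i, control = best)
    }
  }
  do.call(rbind, res)
}

# Cox partial log-likelihood for one covariate, no ties (written directly
# from the definition; the independent oracle for coxph-backed fits)
cox_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
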
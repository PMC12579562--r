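#' Configuration for the waitlist microsimulation
#'
#' A closed cohort of candidates moves yearly among three states — waitlist,
#' transplanted, dead — with year-specific transition probabilities from a
#' [generate_waitlist_schedule()]-style schedule. Under the `path2_all_single`
#' pathway every dual transplant is performed as two singles, so the yearly
#' transplant probability is multiplied by `1 + dual_fraction(year)` (capped
#' at `1 - p_death`).
#'
#' @param n_candidates cohort size (default 100,000).
#' @param schedule a `waitlist_schedule`; its length sets the horizon.
#' @param pathway "path1_current" or "path2_all_single".
#' @param seed integer seed.
#' @param common_random_numbers reuse one uniform draw per candidate-year
#'   across pathways in [compare_pathways()] (default TRUE).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_candidates = 100000L,
                       schedule = generate_waitlist_schedule(),
                       pathway = c("path1_current", "path2_all_single"),
                       seed = 1L, common_random_numbers = TRUE) {
  pathway <- match.arg(pathway)
  if (n_candidates <= 0) stop("n_candidates must be positive", call. = FALSE)
  validate_waitlist_schedule(schedule)
  structure(list(n_candidates = as.integer(n_candidates), schedule = schedule,
                 pathway = pathway, seed = as.integer(seed),
                 common_random_numbers = isTRUE(common_random_numbers)),
            class = "sim_config")
}

# Pathway-adjusted yearly transplant probabilities.
pathway_p_transplant <- function(schedule, pathway) {
  p <- schedule$p_transplant
  if (pathway == "path2_all_single")
    p <- pmin(1 - schedule$p_death, p * (1 + schedule$dual_fraction))
  if (any(p < 0) || any(p + schedule$p_death > 1 + 1e-12))
    stop("adjusted transition probabilities invalid", call. = FALSE)
  p
}

# Core engine over a pre-drawn uniform matrix (n_candidates x n_years).
# One draw per candidate-year decides the transition with cumulative
# thresholds ordered death, transplant, remain; the fixed order makes the
# two pathways couple monotonically under common random numbers.
run_microsim_core <- function(u, schedule, pathway) {
  n <- nrow(u)
  n_years <- nrow(schedule)
  p_tx <- pathway_p_transplant(schedule, pathway)
  p_death <- schedule$p_death
  state <- integer(n)  # 0 waitlist, 1 transplanted, 2 dead
  per_year <- data.frame(year = schedule$year, n_waitlist = integer(n_years),
                         n_transplanted_cum = integer(n_years),
                         n_dead_cum = integer(n_years))
  for (y in seq_len(n_years)) {
    active <- state == 0L
    uy <- u[, y]
    dies <- active & uy < p_death[y]
    tx <- active & !dies & uy < p_death[y] + p_tx[y]
    state[dies] <- 2L
    state[tx] <- 1L
    per_year$n_waitlist[y] <- sum(state == 0L)
    per_year$n_transplanted_cum[y] <- sum(state == 1L)
    per_year$n_dead_cum[y] <- sum(state == 2L)
  }
  structure(list(per_year = per_year,
                 total_waitlist_deaths = per_year$n_dead_cum[n_years],
                 total_transplants = per_year$n_transplanted_cum[n_years],
                 n_candidates = n, pathway = pathway),
            class = "sim_result")
}

#' Run the waitlist microsimulation for one pathway
#'
#' @param config a [sim_config()].
#' @return An object of class `sim_result`: `per_year` (year, waitlist count,
#'   cumulative transplants, cumulative deaths — the three counts sum to the
#'   cohort size every year), `total_waitlist_deaths`, `total_transplants`.
#' @export
run_microsim <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  u <- matrix(stats::runif(config$n_candidates * nrow(config$schedule)),
              nrow = config$n_candidates)
  run_microsim_core(u, config$schedule, config$pathway)
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Waitlist microsimulation (%s): %d candidates, %d years\n",
              x$pathway, x$n_candidates, nrow(x$per_year)))
  cat(sprintf("  waitlist deaths: %d   transplants: %d   still listed: %d\n",
              x$total_waitlist_deaths, x$total_transplants,
              x$per_year$n_waitlist[nrow(x$per_year)]))
  invisible(x)
}

#' Compare the current and all-single allocation pathways
#'
#' Runs the microsimulation under Path 1 (current allocation) and Path 2
#' (all dual transplants performed as singles, raising yearly transplant
#' probabilities). With common random numbers each candidate reuses the same
#' uniform draws in both pathways, which couples the runs: no candidate can
#' fare worse under Path 2, so the death reduction is nonnegative seed by
#' seed.
#'
#' @param config a [sim_config()] (its `pathway` field is ignored).
#' @return list with `path1`, `path2` (both `sim_result`),
#'   `relative_death_reduction` (percent, `(d1 - d2) / d1 * 100`; `NA` with
#'   `degenerate = TRUE` when Path 1 has no deaths) and
#'   `additional_transplants`.
#' @export
compare_pathways <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_years <- nrow(config$schedule)
  u1 <- matrix(stats::runif(config$n_candidates * n_years),
               nrow = config$n_candidates)
  u2 <- if (config$common_random_numbers) u1 else
    matrix(stats::runif(config$n_candidates * n_years),
           nrow = config$n_candidates)
  r1 <- run_microsim_core(u1, config$schedule, "path1_current")
  r2 <- run_microsim_core(u2, config$schedule, "path2_all_single")
  d1 <- r1$total_waitlist_deaths
  d2 <- r2$total_waitlist_deaths
  degenerate <- d1 == 0
  list(path1 = r1, path2 = r2,
       relative_death_reduction = if (degenerate) NA_real_ else
         100 * (d1 - d2) / d1,
       additional_transplants = r2$total_transplants - r1$total_transplants,
       degenerate = degenerate)
}

#' Analytic Markov-chain expectation for a constant schedule
#'
#' Expected cumulative waitlist deaths and transplants for the three-state
#' chain with constant yearly probabilities; used as the closed-form check of
#' the stochastic engine.
#'
#' @param n_candidates cohort size.
#' @param p_transplant,p_death constant yearly probabilities.
#' @param n_years horizon.
#' @return list with `expected_deaths`, `expected_transplants`,
#'   `sd_deaths` (binomial-sum standard deviation of the death count).
#' @export
markov_expected_outcomes <- function(n_candidates, p_transplant, p_death,
                                     n_years) {
  stay <- 1 - p_transplant - p_death
  if (stay < 0) stop("p_transplant + p_death must be <= 1", call. = FALSE)
  years <- seq_len(n_years)
  p_die_cum <- p_death * sum(stay^(years - 1))
  p_tx_cum <- p_transplant * sum(stay^(years - 1))
  list(expected_deaths = n_candidates * p_die_cum,
       expected_transplants = n_candidates * p_tx_cum,
       sd_deaths = sqrt(n_candidates * p_die_cum * (1 - p_die_cum)))
}
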
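#' Default propensity-model covariate list
#'
#' The variables of the group-comparison demographic table, which is the set
#' the propensity model balances.
#' @return character vector of registry column names.
#' @export
default_propensity_covariates <- function() {
  c("donor_age", "kdri", "pump", "donor_female", "cit_hours",
    "glomerulosclerosis", "inotropic_support", "sharing", "distance_miles",
    "recipient_age", "epts", "dialysis_group", "pvd", "renal_diagnosis",
    "bmi", "cpra", "abo_incompatible", "hla_mismatch", "induction",
    "steroids_maintenance")
}

#' Fit the propensity-score model
#'
#' Maximum-likelihood logistic regression (logit link, iteratively reweighted
#' least squares) of transplant group (dual = 1) on the covariates.
#' Categorical covariates enter as reference-coded indicators (reference =
#' first factor level).
#'
#' With `flexible = TRUE` (the default) continuous covariates also enter
#' through quadratic and, when strictly positive, log-scale terms, and
#' zero-inflated percent scales get a zero indicator. Group differences in a
#' covariate's spread or shape — pervasive in this registry — make the true
#' log odds nonlinear in the covariate, and the flexible terms let the fitted
#' score absorb that; matching on a misspecified linear score leaves residual
#' imbalance that no ratio fixes. `flexible = FALSE` gives the plain linear
#' predictor.
#'
#' @param records registry data frame with a `group` column.
#' @param covariates character vector of covariate column names.
#' @param flexible add quadratic/log/zero terms for continuous covariates.
#' @return An object of class `propensity_model`: `coefficients` (named,
#'   excluding intercept), `intercept`, `converged`, `n_iterations`,
#'   `log_likelihood`, `scores` (fitted propensity per record, in (0,1)) and
#'   the underlying `fit`.
#' @export
fit_propensity <- function(records, covariates = default_propensity_covariates(),
                           flexible = TRUE) {
  covariates <- intersect(covariates, names(records))
  if (length(covariates) == 0) stop("no covariates available", call. = FALSE)
  y <- as.integer(records$group == "dual")
  if (length(unique(y)) != 2)
    stop("both groups must be present to fit a propensity model", call. = FALSE)
  dat <- records[, covariates, drop = FALSE]
  dat$.y <- y
  terms <- unlist(lapply(covariates, function(v)
    propensity_terms(dat[[v]], v, flexible)))
  fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  fit <- stats::glm(fml, data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient propensity design; aliased terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  p <- stats::fitted(fit)
  # under (quasi-)complete separation every treated unit's fitted probability
  # is driven to 1 and every control's to 0; tiny fitted values for SOME
  # controls are expected and benign at low treated prevalence
  eps <- 1e-6
  separated <- min(p[y == 1]) > 1 - eps && max(p[y == 0]) < eps
  if (!fit$converged || separated) {
    cf_all <- stats::coef(fit)[-1]
    sds <- vapply(colnames(stats::model.matrix(fit))[-1],
                  function(v) stats::sd(stats::model.matrix(fit)[, v]),
                  numeric(1))
    worst <- names(which.max(abs(cf_all * sds)))
    stop("propensity model did not converge (possible perfect separation); ",
         "offending covariate: ", worst, call. = FALSE)
  }
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  cf <- stats::coef(fit)
  structure(list(coefficients = cf[-1], intercept = unname(cf[1]),
                 formula = fml,
                 converged = fit$converged, n_iterations = fit$iter,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 scores = as.numeric(p), fit = fit),
            class = "propensity_model")
}

# Model terms for one covariate. Factors/logicals enter as-is; numeric
# covariates with few distinct values stay linear (a squared binary indicator
# would be aliased); rich continuous covariates enter as a quadratic — on the
# log scale when strictly positive and right-skewed, else on the natural
# scale — and a zero point mass gets its own indicator.
propensity_terms <- function(x, name, flexible) {
  if (!is.numeric(x) || !flexible) return(name)
  ux <- unique(x[!is.na(x)])
  if (length(ux) <= 10) return(name)
  xo <- x[!is.na(x)]
  skew <- function(v) mean((v - mean(v))^3) / stats::sd(v)^3
  use_log <- min(ux) > 0 && abs(skew(log(xo))) < abs(skew(xo))
  terms <- if (use_log)
    c(sprintf("log(%s)", name), sprintf("I(log(%s)^2)", name))
  else c(name, sprintf("I(%s^2)", name))
  if (mean(x == 0, na.rm = TRUE) > 0.01)
    terms <- c(terms, sprintf("I(%s == 0)", name))
  terms
}

#' Greedy k:1 nearest-neighbor matching on the logit propensity score
#'
#' Treated units are processed hardest-first (descending propensity score,
#' ties broken by a seeded random shuffle); for each treated unit its `ratio`
#' nearest unused controls by absolute difference in logit(score) are taken
#' before moving on (matching without replacement). Deterministic given the
#' seed.
#'
#' @param scores named numeric vector (or data frame column) of propensity
#'   scores for all units, in (0,1).
#' @param treated_ids,control_ids identifiers indexing into `scores`.
#' @param ratio controls per treated unit (k >= 1).
#' @param seed integer seed for tie-breaking.
#' @param partial if `TRUE`, a control shortfall yields a partially matched
#'   cohort instead of an error.
#' @return An object of class `matched_cohort`: `ratio`, `pairs` (data frame
#'   `treated_id`, `control_id`, `pair_index`), `n_treated`, `n_control`, and
#'   `balance` (filled by [match_balance()] / [select_matching_ratio()]).
#' @export
nearest_neighbor_match <- function(scores, treated_ids, control_ids,
                                   ratio = 1L, seed = 1L, partial = FALSE) {
  stopifnot(ratio >= 1)
  if (anyDuplicated(c(treated_ids, control_ids)))
    stop("treated and control ids must be disjoint and unique", call. = FALSE)
  if (length(control_ids) < ratio * length(treated_ids) && !partial)
    stop(sprintf(
      "not enough controls: need %d, have %d (shortfall %d)",
      ratio * length(treated_ids), length(control_ids),
      ratio * length(treated_ids) - length(control_ids)), call. = FALSE)
  s_t <- scores[as.character(treated_ids)]
  s_c <- scores[as.character(control_ids)]
  if (anyNA(s_t) || anyNA(s_c))
    stop("scores missing for some ids", call. = FALSE)
  lt <- stats::qlogis(pmin(pmax(s_t, 1e-12), 1 - 1e-12))
  lc <- stats::qlogis(pmin(pmax(s_c, 1e-12), 1 - 1e-12))

  set.seed(seed)
  shuffle <- sample.int(length(treated_ids))  # seeded tie-break
  ord <- shuffle[order(-lt[shuffle])]

  # dist_work holds logit scores; used controls are retired by setting +Inf
  dist_work <- lc
  n_pick <- min(ratio * length(treated_ids), length(control_ids))
  out_t <- integer(n_pick); out_c <- integer(n_pick); out_k <- integer(n_pick)
  np <- 0L
  for (i in ord) {
    d <- abs(dist_work - lt[i])
    for (k in seq_len(ratio)) {
      j <- which.min(d)
      if (!is.finite(d[j])) {
        if (partial) break
        stop("controls exhausted during matching", call. = FALSE)
      }
      d[j] <- Inf
      dist_work[j] <- Inf
      np <- np + 1L
      out_t[np] <- i; out_c[np] <- j; out_k[np] <- k
    }
  }
  pairs <- data.frame(treated_id = as.character(treated_ids)[out_t[seq_len(np)]],
                      control_id = as.character(control_ids)[out_c[seq_len(np)]],
                      pair_index = out_k[seq_len(np)], stringsAsFactors = FALSE)
  structure(list(ratio = as.integer(ratio), pairs = pairs,
                 n_treated = length(treated_ids), n_control = nrow(pairs),
                 balance = NULL),
            class = "matched_cohort")
}

#' Standardized mean difference between two samples
#'
#' Continuous: `(mean_a - mean_b) / sqrt((var_a + var_b) / 2)`. Binary:
#' `(p_a - p_b) / sqrt((p_a(1-p_a) + p_b(1-p_b)) / 2)`. Factors are expanded
#' into per-level binary SMDs and the maximum absolute value is returned.
#' A zero pooled variance with unequal means yields `Inf` (flagged by sign).
#'
#' @param values_a,values_b samples from the two groups.
#' @param type "continuous", "binary", or "auto" (default; inferred from the
#'   data type).
#' @return the (signed) standardized mean difference; for factors, the
#'   maximum absolute per-level SMD.
#' @export
standardized_mean_difference <- function(values_a, values_b, type = "auto") {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (type == "auto") {
    if (is.factor(values_a) || is.character(values_a)) type <- "categorical"
    else if (is.logical(values_a)) type <- "binary"
    else type <- "continuous"
  }
  smd_num <- function(a, b, va, vb) {
    pooled <- sqrt((va + vb) / 2)
    diff <- mean(a) - mean(b)
    if (pooled == 0) return(if (diff == 0) 0 else sign(diff) * Inf)
    diff / pooled
  }
  switch(type,
    continuous = smd_num(values_a, values_b,
                         stats::var(values_a), stats::var(values_b)),
    binary = {
      pa <- mean(as.logical(values_a)); pb <- mean(as.logical(values_b))
      smd_num(as.numeric(as.logical(values_a)), as.numeric(as.logical(values_b)),
              pa * (1 - pa), pb * (1 - pb))
    },
    categorical = {
      levs <- union(unique(as.character(values_a)), unique(as.character(values_b)))
      per <- vapply(levs, function(l)
        standardized_mean_difference(as.character(values_a) == l,
                                     as.character(values_b) == l,
                                     type = "binary"), numeric(1))
      unname(per[which.max(abs(per))])
    },
    stop("unknown SMD type: ", type, call. = FALSE))
}

#' Covariate balance table for a matched cohort
#'
#' @param records registry data frame.
#' @param cohort a `matched_cohort`.
#' @param covariates covariate names to assess.
#' @param id_col identifier column (default "id").
#' @return data frame `covariate`, `smd_before`, `smd_after` (SMDs of dual vs
#'   single before matching, and matched treated vs matched controls after).
#' @export
match_balance <- function(records, cohort,
                          covariates = default_propensity_covariates(),
                          id_col = "id") {
  covariates <- intersect(covariates, names(records))
  ids <- records[[id_col]]
  dual <- records$group == "dual"
  t_idx <- match(unique(cohort$pairs$treated_id), ids)
  c_idx <- match(cohort$pairs$control_id, ids)
  out <- do.call(rbind, lapply(covariates, function(v) {
    x <- records[[v]]
    data.frame(covariate = v,
               smd_before = standardized_mean_difference(x[dual], x[!dual]),
               smd_after = standardized_mean_difference(x[t_idx], x[c_idx]))
  }))
  rownames(out) <- NULL
  out
}

#' Select the matching ratio by balance
#'
#' Fits the propensity model once, performs greedy nearest-neighbor matching
#' at each candidate ratio in the order given, and returns the largest ratio
#' whose post-match balance satisfies `max |SMD| <= threshold`. When no ratio
#' balances, the best-balanced cohort is returned with `balanced = FALSE`.
#'
#' @param records registry data frame (with `id` and `group` columns).
#' @param covariates propensity/balance covariates.
#' @param ratios candidate ratios, evaluated in order (default 1, 2, 3).
#' @param threshold balance threshold on |SMD| (default 0.1).
#' @param seed matching tie-break seed.
#' @return The selected `matched_cohort`, with `balance` (its balance table),
#'   `balanced` flag, `max_abs_smd`, `model` (the propensity fit) and
#'   `candidates`, the per-ratio balance summary.
#' @export
select_matching_ratio <- function(records,
                                  covariates = default_propensity_covariates(),
                                  ratios = c(1L, 2L, 3L), threshold = 0.1,
                                  seed = 1L) {
  stopifnot(length(ratios) >= 1)
  model <- fit_propensity(records, covariates)
  scores <- stats::setNames(model$scores, records$id)
  treated <- records$id[records$group == "dual"]
  controls <- records$id[records$group == "single"]
  cands <- list()
  for (r in ratios) {
    cohort <- nearest_neighbor_match(scores, treated, controls, ratio = r,
                                     seed = seed)
    bal <- match_balance(records, cohort, covariates)
    cohort$balance <- bal
    cohort$max_abs_smd <- max(abs(bal$smd_after))
    cands[[as.character(r)]] <- cohort
  }
  maxsmd <- vapply(cands, function(co) co$max_abs_smd, numeric(1))
  ok <- maxsmd <= threshold
  if (any(ok)) {
    pick <- cands[[max(which(ok))]]
    pick$balanced <- TRUE
  } else {
    pick <- cands[[which.min(maxsmd)]]
    pick$balanced <- FALSE
  }
  pick$model <- model
  pick$candidates <- data.frame(ratio = as.integer(names(cands)),
                                max_abs_smd = unname(maxsmd),
                                balanced = unname(ok))
  pick
}

#' Extract the matched records for outcome analysis
#'
#' @param records registry data frame.
#' @param cohort a `matched_cohort`.
#' @param id_col identifier column.
#' @return the registry rows of matched treated and control units (treated
#'   rows appear once each).
#' @export
matched_records <- function(records, cohort, id_col = "id") {
  ids <- c(unique(cohort$pairs$treated_id), cohort$pairs$control_id)
  records[match(ids, records[[id_col]]), , drop = FALSE]
}
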
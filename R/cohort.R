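#' Apply the study's cohort inclusion filters
#'
#' Retains adult (>= 18 years) recipients of a deceased-donor single or dual
#' kidney transplant that is not a pediatric en bloc transplant, with a
#' reported KDRI and survival data. Exclusion rules are applied in a fixed,
#' documented order — recipient age, donor type (living), en bloc, missing
#' KDRI, missing survival data — and a record failing several rules is counted
#' once, under the first failing rule, so the report's exclusion counts sum
#' exactly to `n_input - n_output`.
#'
#' @param records registry data frame.
#' @return A list with `records` (the retained rows) and `report`, a
#'   `cohort_filter_report` with `n_input`, `n_excluded_by_rule` (named
#'   integer vector in rule order) and `n_output`.
#' @export
filter_cohort <- function(records) {
  rules <- list(
    recipient_under_18 = function(r) !is.na(r$recipient_age) & r$recipient_age < 18,
    living_donor = function(r) isTRUE_vec(r$living_donor),
    en_bloc = function(r) isTRUE_vec(r$en_bloc),
    missing_kdri = function(r) is.na(r$kdri),
    missing_survival = function(r) is.na(r$time_death) | is.na(r$event_death) |
      is.na(r$time_graftfail) | is.na(r$event_graftfail)
  )
  n_input <- nrow(records)
  excluded <- rep(FALSE, n_input)
  counts <- integer(length(rules))
  names(counts) <- names(rules)
  for (i in seq_along(rules)) {
    fails <- rules[[i]](records) & !excluded
    counts[i] <- sum(fails)
    excluded <- excluded | fails
  }
  report <- structure(
    list(n_input = n_input, n_excluded_by_rule = counts,
         n_output = n_input - sum(counts)),
    class = "cohort_filter_report")
  list(records = records[!excluded, , drop = FALSE], report = report)
}

isTRUE_vec <- function(x) {
  if (is.null(x)) return(FALSE)
  !is.na(x) & as.logical(x)
}

#' @export
print.cohort_filter_report <- function(x, ...) {
  cat("Cohort filter:", x$n_input, "records in,", x$n_output, "retained\n")
  for (nm in names(x$n_excluded_by_rule))
    cat(sprintf("  excluded (%s): %d\n", nm, x$n_excluded_by_rule[[nm]]))
  invisible(x)
}

#' Single imputation of BMI, cold ischemia time and length of stay
#'
#' Mirrors the study's imputation: BMI is imputed by least-squares linear
#' regression on recipient age, sex and race/ethnicity (race entering as
#' reference-coded indicators, reference = first factor level); CIT by linear
#' regression on sharing type and donor-to-center distance; length of stay by
#' the median of observed values. Observed values are never altered.
#'
#' @param records registry data frame with columns `bmi`, `recipient_age`,
#'   `recipient_female`, `race`, `cit_hours`, `sharing`, `distance_miles`,
#'   `los_days`.
#' @return The records with no missing values in `bmi`, `cit_hours`,
#'   `los_days`.
#' @export
impute_missing <- function(records) {
  impute_lm <- function(data, response, rhs) {
    miss <- is.na(data[[response]])
    if (!any(miss)) return(data)
    if (all(miss))
      stop("cannot impute '", response, "': all values missing", call. = FALSE)
    fml <- stats::as.formula(paste(response, "~", rhs))
    fit <- stats::lm(fml, data = data[!miss, , drop = FALSE])
    pred <- stats::predict(fit, newdata = data[miss, , drop = FALSE])
    data[[response]][miss] <- as.numeric(pred)
    data
  }
  records <- impute_lm(records, "bmi", "recipient_age + recipient_female + race")
  records <- impute_lm(records, "cit_hours", "sharing + distance_miles")
  miss_los <- is.na(records$los_days)
  if (any(miss_los)) {
    if (all(miss_los))
      stop("cannot impute 'los_days': all values missing", call. = FALSE)
    records$los_days[miss_los] <- stats::median(records$los_days[!miss_los])
  }
  records
}

#' Compare one variable between the dual and single groups
#'
#' Continuous variables: Wilcoxon rank-sum test with the tie-corrected normal
#' approximation (no continuity correction), summarised as median (IQR).
#' Categorical/logical variables: Pearson chi-square test of independence
#' without continuity correction, summarised as n (%) per level.
#'
#' @param records registry data frame with a two-level `group` column.
#' @param variable column name to compare.
#' @return A list with `variable`, `type`, `statistic`, `p_value`,
#'   `degenerate` (TRUE when the variable is constant across both groups, in
#'   which case the statistic is 0 and p = 1), and `summary`, a data frame of
#'   per-group summaries.
#' @export
compare_groups <- function(records, variable) {
  g <- records$group
  if (length(unique(g)) != 2)
    stop("compare_groups requires exactly two groups", call. = FALSE)
  x <- records[[variable]]
  if (is.null(x)) stop("no such variable: ", variable, call. = FALSE)
  keep <- !is.na(x)
  x <- x[keep]; g <- factor(g[keep], levels = c("dual", "single"))

  if (is.numeric(x)) {
    if (length(unique(x)) == 1L)
      return(degenerate_comparison(variable, "continuous", x, g))
    wt <- stats::wilcox.test(x ~ g, exact = FALSE, correct = FALSE)
    summ <- do.call(rbind, lapply(levels(g), function(lev) {
      v <- x[g == lev]
      data.frame(group = lev, n = length(v), median = stats::median(v),
                 q1 = unname(stats::quantile(v, 0.25)),
                 q3 = unname(stats::quantile(v, 0.75)))
    }))
    list(variable = variable, type = "continuous",
         statistic = unname(wt$statistic), p_value = wt$p.value,
         degenerate = FALSE, summary = summ)
  } else {
    x <- if (is.logical(x)) factor(x, levels = c(FALSE, TRUE)) else factor(x)
    x <- droplevels(x)
    if (nlevels(x) < 2)
      return(degenerate_comparison(variable, "categorical", x, g))
    tab <- table(g, x)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    summ <- do.call(rbind, lapply(levels(g), function(lev) {
      counts <- tab[lev, ]
      data.frame(group = lev, level = colnames(tab),
                 n = as.integer(counts),
                 percent = round(100 * as.integer(counts) / sum(counts), 1))
    }))
    list(variable = variable, type = "categorical",
         statistic = unname(ct$statistic), p_value = ct$p.value,
         degenerate = FALSE, summary = summ)
  }
}

degenerate_comparison <- function(variable, type, x, g) {
  summ <- data.frame(group = levels(g),
                     n = as.integer(table(g)))
  list(variable = variable, type = type, statistic = 0, p_value = 1,
       degenerate = TRUE, summary = summ)
}

#' Group-comparison descriptive table
#'
#' Builds the demographic-table-style comparison (median (IQR) or n (%) per
#' group plus a p-value) for a set of variables.
#'
#' @param records registry data frame.
#' @param variables character vector of column names.
#' @return A data frame with one row per variable (continuous) or per
#'   variable level (categorical): `variable`, `level`, `dual`, `single`,
#'   `p_value` (repeated within a variable's levels).
#' @export
descriptive_table <- function(records, variables) {
  rows <- lapply(variables, function(v) {
    cmp <- compare_groups(records, v)
    p <- format_pvalue(cmp$p_value)
    if (cmp$type == "continuous") {
      s <- cmp$summary
      fmt <- function(row) sprintf("%.1f (%.1f, %.1f)", row$median, row$q1, row$q3)
      data.frame(variable = v, level = "",
                 dual = fmt(s[s$group == "dual", ]),
                 single = fmt(s[s$group == "single", ]),
                 p_value = p)
    } else if (!cmp$degenerate) {
      s <- cmp$summary
      lv <- unique(s$level)
      do.call(rbind, lapply(lv, function(l) {
        d <- s[s$group == "dual" & s$level == l, ]
        sg <- s[s$group == "single" & s$level == l, ]
        data.frame(variable = v, level = as.character(l),
                   dual = sprintf("%d (%.1f%%)", d$n, d$percent),
                   single = sprintf("%d (%.1f%%)", sg$n, sg$percent),
                   p_value = p)
      }))
    } else {
      data.frame(variable = v, level = "", dual = "constant",
                 single = "constant", p_value = p)
    }
  })
  do.call(rbind, rows)
}

format_pvalue <- function(p) {
  if (is.na(p)) return("NA")
  if (p < 0.001) "< 0.001" else sprintf("%.3f", p)
}
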
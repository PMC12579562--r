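#' Read and write registry CSV files
#'
#' Registries are plain CSV with one row per transplant and the column set
#' produced by [generate_registry()]. Factor columns are restored from
#' character on read; logical flags are stored as TRUE/FALSE.
#'
#' @param records registry data frame.
#' @param path file path.
#' @return `read_registry()` returns the registry data frame;
#'   `write_registry()` returns `path` invisibly.
#' @export
write_registry <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"group" %in% names(rec))
    stop("malformed registry: missing required column 'group'", call. = FALSE)
  fac <- intersect(c("dialysis_group", "renal_diagnosis", "glomerulosclerosis",
                     "sharing", "induction", "race"), names(rec))
  for (nm in fac) rec[[nm]] <- factor(rec[[nm]])
  rec
}

#' Read and write waitlist schedules as YAML
#'
#' The schedule file is a structured key-value document with one entry per
#' year carrying `year`, `p_transplant`, `p_death` and `dual_fraction`.
#'
#' @param schedule a `waitlist_schedule` data frame.
#' @param path file path.
#' @return `read_waitlist_schedule()` returns a validated
#'   `waitlist_schedule`; `write_waitlist_schedule()` returns `path`
#'   invisibly.
#' @export
write_waitlist_schedule <- function(schedule, path) {
  validate_waitlist_schedule(schedule)
  rows <- lapply(seq_len(nrow(schedule)), function(i)
    list(year = as.integer(schedule$year[i]),
         p_transplant = schedule$p_transplant[i],
         p_death = schedule$p_death[i],
         dual_fraction = schedule$dual_fraction[i]))
  yaml::write_yaml(list(schedule = rows), path, precision = 15)
  invisible(path)
}

#' @rdname write_waitlist_schedule
#' @export
read_waitlist_schedule <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$schedule))
    stop("schedule file must contain a top-level 'schedule' list", call. = FALSE)
  sched <- do.call(rbind, lapply(doc$schedule, function(r)
    data.frame(year = r$year, p_transplant = r$p_transplant,
               p_death = r$p_death, dual_fraction = r$dual_fraction)))
  class(sched) <- c("waitlist_schedule", "data.frame")
  validate_waitlist_schedule(sched)
  sched
}
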
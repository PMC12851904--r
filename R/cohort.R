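# Eligibility rules, study cohorts, outcome ascertainment, running variable.

PROGRAM_START <- as.Date("2013-09-01")
DEFAULT_THRESHOLD <- as.Date("1933-09-02")
DOB_SPAN <- as.Date(c("1925-09-01", "1942-09-01"))

# Dementia ICD-style code set used when classifying causes of death. A custom
# mapping can be supplied wherever a `code_sets` argument is accepted, either
# as a list or as a YAML file (outcome name -> character vector of codes).
default_code_sets <- function() {
  list(dementia = c("F00", "F01", "F02", "F03", "G30", "G31.8"))
}

#' Read outcome code sets from a YAML mapping
#'
#' @param path YAML file mapping outcome names to character vectors of codes.
#' @return named list of character vectors.
#' @export
read_code_sets <- function(path) {
  sets <- yaml::read_yaml(path)
  lapply(sets, as.character)
}

#' Assign program eligibility from date of birth
#'
#' Encodes the staggered catch-up schedule of the national rollout: persons
#' aged 80+ at program start (born on or before 1933-09-01) never became
#' eligible; younger birth cohorts were offered the vaccine in program years
#' one to four according to fixed date-of-birth windows; from April 2017 the
#' rule switched to eligibility from the 78th until the 80th birthday.
#'
#' @param date_of_birth `Date` vector within the supported span
#'   1925-09-01 to 1942-09-01.
#' @return a tibble with columns `cohort_label` (factor: `never_eligible`,
#'   `catchup_year_1` .. `catchup_year_4`, `post_2017_rule`),
#'   `eligibility_start`, `eligibility_end` (`Date`, `NA` for the never
#'   eligible).
#' @export
assign_eligibility <- function(date_of_birth) {
  dob <- as.Date(date_of_birth)
  if (any(is.na(dob))) stop("date_of_birth contains missing values", call. = FALSE)
  if (any(dob < DOB_SPAN[1] | dob > DOB_SPAN[2])) {
    stop("date_of_birth outside supported span 1925-09-01..1942-09-01", call. = FALSE)
  }
  labels <- c("never_eligible", paste0("catchup_year_", 1:4), "post_2017_rule")
  cuts <- as.Date(c("1933-09-02", "1934-09-02", "1936-09-02", "1937-09-02", "1938-09-02"))
  idx <- findInterval(dob, cuts) + 1L # 1 = never eligible
  label <- factor(labels[idx], levels = labels)
  starts <- as.Date(c(NA, "2013-09-01", "2014-09-01", "2015-09-01", "2016-09-01", NA))
  ends   <- as.Date(c(NA, "2014-08-31", "2015-08-31", "2016-08-31", "2017-08-31", NA))
  start <- starts[idx]
  end <- ends[idx]
  post <- idx == 6L
  if (any(post)) {
    # eligible from the 78th birthday (no earlier than 2017-04-01) to the 80th
    start[post] <- pmax(add_years(dob[post], 78L), as.Date("2017-04-01"))
    end[post] <- add_years(dob[post], 80L) - 1L
  }
  tibble::tibble(cohort_label = label, eligibility_start = start, eligibility_end = end)
}

#' Center the weekly running variable on the eligibility threshold
#'
#' Converts Monday-anchored weeks of birth into signed whole weeks from the
#' date-of-birth eligibility threshold: 0 is the first week on the eligible
#' side, negative values lie on the ineligible side.
#'
#' The week containing the threshold date belongs wholly to neither side.
#' `straddle_rule = "majority"` (default) assigns it to the side holding the
#' majority of its seven days; `"eligible"`/`"ineligible"` force a side and
#' `"drop"` returns `NA` for that week.
#'
#' @param week_of_birth `Date` vector of Mondays.
#' @param threshold_date the eligibility threshold (`Date`).
#' @param straddle_rule one of `"majority"`, `"eligible"`, `"ineligible"`,
#'   `"drop"`.
#' @return integer vector of signed weeks.
#' @export
center_running_variable <- function(week_of_birth,
                                    threshold_date = DEFAULT_THRESHOLD,
                                    straddle_rule = c("majority", "eligible", "ineligible", "drop")) {
  straddle_rule <- match.arg(straddle_rule)
  wob <- as.Date(week_of_birth)
  if (!all(is_monday(wob))) stop("week_of_birth must be Mondays", call. = FALSE)
  threshold_date <- as.Date(threshold_date)
  t_mon <- week_monday(threshold_date)
  raw <- as.integer(wob - t_mon) %/% 7L
  n_elig_days <- 7L - as.integer(threshold_date - t_mon)
  if (straddle_rule == "majority") {
    straddle_rule <- if (n_elig_days >= 4L) "eligible" else "ineligible"
  }
  if (n_elig_days == 7L) straddle_rule <- "eligible" # threshold on a Monday: no straddle
  switch(straddle_rule,
    eligible = raw,
    ineligible = raw - 1L,
    drop = ifelse(raw == 0L, NA_integer_, ifelse(raw > 0L, raw - 1L, raw))
  )
}

#' Build a study cohort from baseline cognitive status
#'
#' `no_cognitive_impairment` keeps persons with no record of any cognitive
#' impairment before program start (the cohort for incident MCI analyses);
#' `living_with_dementia` keeps persons with a dementia diagnosis before
#' program start (the cohort for dementia-death analyses). The two cohorts are
#' disjoint: persons with non-dementia cognitive impairment fall in neither.
#'
#' @param persons person table (see [generate_cohort()] for the schema).
#' @param which cohort rule.
#' @return filtered copy of `persons`.
#' @export
build_cohort <- function(persons, which = c("no_cognitive_impairment", "living_with_dementia")) {
  which <- match.arg(which)
  keep <- switch(which,
    no_cognitive_impairment = !persons$baseline_cognitive_impairment,
    living_with_dementia = persons$baseline_dementia
  )
  persons[keep, , drop = FALSE]
}

#' Specify a follow-up outcome
#'
#' @param name outcome name. Built-ins: `mci`, `mci_no_dementia_3m`,
#'   `mci_no_dementia_6m`, `dementia`, `dementia_alzheimer`,
#'   `dementia_vascular`, `dementia_mixed`, `dementia_other`,
#'   `death_due_to_dementia`, `death_nondementia`, `death_all_cause`,
#'   `vaccination` (receipt indicator), and `nc_<condition>` for negative
#'   control conditions carried by the person table.
#' @param follow_up_years length of the ascertainment window (1--9).
#' @param grace_period_weeks weeks after the index date excluded from
#'   ascertainment (time-to-immunity allowance); shortens time at risk, not
#'   the calendar end of the window.
#' @param index_date_policy `"program_start"` dates follow-up from the program
#'   start for everyone; `"own_eligibility_date"` from each person's own
#'   eligibility date (never-eligibles receive the index date of their
#'   mirror-image eligible person, and analyses should add rollout-cohort
#'   fixed effects).
#' @param window_shift_years shifts the whole window by whole years (0 for
#'   primary analyses, -9 for the pre-period confounding test, +/-k for
#'   placebo thresholds).
#' @param month_days days per month used by the `mci_no_dementia_*` rules
#'   (30.44-day blocks by default).
#' @return an `outcome_spec` list.
#' @export
outcome_spec <- function(name,
                         follow_up_years = 9L,
                         grace_period_weeks = 0L,
                         index_date_policy = c("program_start", "own_eligibility_date"),
                         window_shift_years = 0L,
                         month_days = 30.44) {
  stopifnot(is.character(name), length(name) == 1L)
  follow_up_years <- check_count(follow_up_years, "follow_up_years")
  if (follow_up_years > 9L) stop_field("follow_up_years", "must be between 1 and 9")
  grace_period_weeks <- check_count(grace_period_weeks, "grace_period_weeks", positive = FALSE)
  structure(
    list(
      name = name,
      follow_up_years = follow_up_years,
      grace_period_weeks = grace_period_weeks,
      index_date_policy = match.arg(index_date_policy),
      window_shift_years = as.integer(window_shift_years),
      month_days = month_days
    ),
    class = "outcome_spec"
  )
}

# date column(s) holding the qualifying event for each outcome name. The
# `post` column is the follow-up event record, to which cause/type filters
# apply; `pre` is the outcome-specific pre-period history column (already
# filtered by definition), consulted whenever a shifted window reaches before
# program start so that such windows see a continuous event history.
outcome_event_dates <- function(persons, name) {
  col <- function(nm) {
    if (!nm %in% names(persons)) {
      stop(sprintf("person table lacks column `%s` needed for outcome `%s`", nm, name),
           call. = FALSE)
    }
    as.Date(persons[[nm]])
  }
  pre_col <- function(nm) {
    nm <- paste0("pre_", nm, "_date")
    if (nm %in% names(persons)) as.Date(persons[[nm]]) else as.Date(rep(NA, nrow(persons)))
  }
  base <- sub("^mci_no_dementia_[36]m$", "mci", name)
  base <- sub("^dementia_(alzheimer|vascular|mixed|other)$", "dementia", base)
  post <- switch(base,
    mci = col("mci_date"),
    dementia = col("dementia_date"),
    death_due_to_dementia = ,
    death_nondementia = ,
    death_all_cause = col("death_date"),
    vaccination = col("vaccination_date"),
    {
      if (grepl("^nc_", base)) {
        col(paste0(base, "_date"))
      } else {
        stop(sprintf("unknown outcome name `%s`", name), call. = FALSE)
      }
    }
  )
  list(post = post, pre = pre_col(name))
}

index_dates <- function(persons, spec) {
  base <- if (spec$index_date_policy == "program_start") {
    rep(PROGRAM_START, nrow(persons))
  } else {
    sched <- assign_eligibility(persons$date_of_birth)
    idx <- sched$eligibility_start
    never <- is.na(idx)
    if (any(never)) {
      # mirror rule: a person born k weeks before the threshold inherits the
      # index date of the eligible person born k weeks after, preserving
      # comparability of age at index across the threshold
      mirrored <- DEFAULT_THRESHOLD + (DEFAULT_THRESHOLD - as.Date(persons$date_of_birth[never]))
      mirrored <- pmin(pmax(mirrored, DOB_SPAN[1]), DOB_SPAN[2])
      idx[never] <- assign_eligibility(mirrored)$eligibility_start
    }
    idx
  }
  add_years(base, spec$window_shift_years)
}

#' Ascertain a binary outcome over a follow-up window
#'
#' Returns 1 when the qualifying event date falls in
#' `[index + shift + grace, index + shift + follow_up_years)`; absence of a
#' record codes 0. Cause-of-death outcomes classify the underlying and
#' contributing causes against the dementia code set; `mci_no_dementia_Km`
#' additionally requires no dementia diagnosis within K months of the MCI
#' record.
#'
#' @param persons person table.
#' @param spec an [outcome_spec()].
#' @param code_sets named list of cause-of-death code sets (see
#'   [read_code_sets()]).
#' @return integer 0/1 vector along the rows of `persons`.
#' @export
ascertain_outcome <- function(persons, spec, code_sets = default_code_sets()) {
  if (is.character(spec)) spec <- outcome_spec(spec)
  stopifnot(inherits(spec, "outcome_spec"))
  idx <- index_dates(persons, spec)
  win_start <- idx + 7L * spec$grace_period_weeks
  win_end <- add_years(idx, spec$follow_up_years) - 1L
  ev <- outcome_event_dates(persons, spec$name)
  # integrity: a dementia diagnosis may not postdate death
  if (all(c("dementia_date", "death_date") %in% names(persons))) {
    bad <- !is.na(persons$dementia_date) & !is.na(persons$death_date) &
      as.Date(persons$dementia_date) > as.Date(persons$death_date)
    if (any(bad)) {
      stop(sprintf("inconsistent event ordering (dementia after death) for %d person(s)",
                   sum(bad)), call. = FALSE)
    }
  }
  in_win <- function(d) !is.na(d) & d >= win_start & d <= win_end
  hit_post <- in_win(ev$post)
  name <- spec$name
  if (grepl("^mci_no_dementia_", name)) {
    k <- as.numeric(sub("^mci_no_dementia_([36])m$", "\\1", name))
    dem <- as.Date(persons$dementia_date)
    mci <- as.Date(persons$mci_date)
    followed <- !is.na(dem) & !is.na(mci) & dem >= mci &
      as.numeric(dem - mci) <= k * spec$month_days
    hit_post <- hit_post & !followed
  } else if (grepl("^dementia_(alzheimer|vascular|mixed|other)$", name)) {
    type <- sub("^dementia_", "", name)
    hit_post <- hit_post & !is.na(persons$dementia_type) & persons$dementia_type == type
  } else if (name == "death_due_to_dementia") {
    hit_post <- hit_post & cause_in_set(persons$underlying_cause, code_sets$dementia)
  } else if (name == "death_nondementia") {
    dem_any <- cause_in_set(persons$underlying_cause, code_sets$dementia) |
      contributing_in_set(persons$contributing_causes, code_sets$dementia)
    hit_post <- hit_post & !dem_any
  }
  as.integer(hit_post | in_win(ev$pre))
}

cause_in_set <- function(cause, set) {
  !is.na(cause) & cause %in% set
}

contributing_in_set <- function(causes, set) {
  if (is.null(causes)) return(logical(0))
  vapply(strsplit(ifelse(is.na(causes), "", causes), ";", fixed = TRUE),
         function(cs) any(cs %in% set), logical(1))
}

#' Assemble an analysis cohort for threshold-based estimation
#'
#' Applies the cohort rule, centers the weekly running variable and ascertains
#' the requested outcome, yielding the flat table consumed by the
#' regression-discontinuity estimators.
#'
#' @param persons person table.
#' @param cohort cohort rule passed to [build_cohort()], or `"all"`.
#' @param outcome an [outcome_spec()] or outcome name.
#' @param threshold_date eligibility threshold.
#' @param straddle_rule see [center_running_variable()].
#' @param code_sets cause-of-death code sets.
#' @return tibble with `person_id`, `centered_wob`, `eligible`, `vaccinated`,
#'   `outcome`, `gender`, `male`, plus all remaining person columns.
#' @export
analysis_cohort <- function(persons,
                            cohort = "no_cognitive_impairment",
                            outcome = "mci",
                            threshold_date = DEFAULT_THRESHOLD,
                            straddle_rule = "majority",
                            code_sets = default_code_sets()) {
  dat <- if (identical(cohort, "all")) persons else build_cohort(persons, cohort)
  x <- center_running_variable(dat$week_of_birth, threshold_date, straddle_rule)
  keep <- !is.na(x)
  dat <- dat[keep, , drop = FALSE]
  x <- x[keep]
  spec <- if (is.character(outcome)) outcome_spec(outcome) else outcome
  out <- tibble::tibble(
    person_id = dat$person_id,
    centered_wob = x,
    eligible = x >= 0L,
    vaccinated = !is.na(dat$vaccination_date),
    outcome = ascertain_outcome(dat, spec, code_sets),
    gender = dat$gender,
    male = as.integer(dat$gender == "male")
  )
  extra <- setdiff(names(dat), names(out))
  tibble::as_tibble(cbind(out, dat[extra]))
}
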
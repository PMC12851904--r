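# Falsification and robustness machinery: placebo thresholds, pre-period
# outcomes, baseline balance, negative controls, robustness grids.

#' Placebo date-of-birth thresholds
#'
#' Re-runs the sharp threshold analysis at the September 2 threshold of other
#' birth years, shifting the follow-up window congruently so that identical
#' age ranges are compared, and truncating follow-up to six years so every
#' shifted window fits the observed period. Bandwidths are re-selected per
#' threshold (the full procedure is repeated, not just the final fit).
#'
#' @param persons person table.
#' @param years placebo threshold birth years.
#' @param outcome outcome name.
#' @param cohort cohort rule.
#' @param follow_up_years follow-up length for all placebo runs.
#' @param config an [rd_config()].
#' @return list with `fits` (per-year `rd_result` or `NULL`) and `summary`
#'   tibble.
#' @export
placebo_thresholds <- function(persons,
                               years = c(1930, 1931, 1932, 1934, 1935, 1936),
                               outcome = "mci",
                               cohort = "no_cognitive_impairment",
                               follow_up_years = 6L,
                               config = rd_config()) {
  fits <- lapply(years, function(yr) {
    threshold <- as.Date(sprintf("%d-09-02", yr))
    spec <- outcome_spec(outcome, follow_up_years = follow_up_years,
                         window_shift_years = yr - 1933L)
    tryCatch({
      ac <- analysis_cohort(persons, cohort, spec, threshold_date = threshold)
      rd_sharp(ac, config = config)
    }, error = function(e) {
      warning(sprintf("placebo year %d omitted: %s", yr, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  })
  names(fits) <- as.character(years)
  list(fits = fits, summary = summarize_rd_fits(fits))
}

summarize_rd_fits <- function(fits) {
  if (length(fits) == 0L) {
    return(tibble::tibble(name = character(0), estimate = numeric(0),
                          estimate_bc = numeric(0), se_robust = numeric(0),
                          ci_lo = numeric(0), ci_hi = numeric(0),
                          p = numeric(0), h = numeric(0), status = character(0)))
  }
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (is.null(f)) {
      tibble::tibble(name = nm, estimate = NA_real_, estimate_bc = NA_real_,
                     se_robust = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                     p = NA_real_, h = NA_real_, status = "failed")
    } else {
      tibble::tibble(name = nm, estimate = f$estimate, estimate_bc = f$estimate_bc,
                     se_robust = f$se_robust, ci_lo = f$ci_robust[1],
                     ci_hi = f$ci_robust[2], p = f$p_robust, h = f$bandwidth_h,
                     status = "ok")
    }
  })
  do.call(rbind, rows)
}

#' Pre-period outcome test
#'
#' The identical threshold analysis with the follow-up window shifted nine
#' years before program start: any jump in pre-period outcome incidence would
#' indicate a pre-existing intervention sharing the threshold.
#'
#' @param persons person table.
#' @param outcome outcome name (the person table must carry the
#'   corresponding pre-period history column).
#' @param cohort cohort rule.
#' @param config an [rd_config()].
#' @return an `rd_result` (estimate exactly 0 with a degenerate-variance
#'   warning when no pre-period events exist).
#' @export
preperiod_test <- function(persons, outcome = "mci",
                           cohort = "no_cognitive_impairment",
                           config = rd_config()) {
  spec <- outcome_spec(outcome, follow_up_years = 9L, window_shift_years = -9L)
  ac <- analysis_cohort(persons, cohort, spec)
  if (stats::var(ac$outcome) == 0) {
    warning("no pre-period events: estimate degenerate at 0 with zero variance",
            call. = FALSE)
    cfg_fixed <- config
    cfg_fixed$bandwidth_policy <- "fixed"
    cfg_fixed$bandwidth <- max(abs(ac$centered_wob)) / 2
    cfg_fixed$bias_bandwidth_policy <- "same_as_h"
    return(rd_sharp(ac, config = cfg_fixed))
  }
  rd_sharp(ac, config = config)
}

#' Baseline balance and negative-control outcome tests
#'
#' One sharp threshold fit per baseline covariate (balance: any jump would
#' indicate sorting or a competing assignment rule) and per negative-control
#' outcome during follow-up (any effect would indicate an intervention not
#' specific to the outcomes of interest). No multiplicity adjustment is
#' applied; the count of significant results is reported next to the count
#' expected by chance.
#'
#' @param persons person table.
#' @param cohort cohort rule.
#' @param covariates baseline covariate columns (defaults to the Charlson
#'   flags and preventive-uptake indicators).
#' @param control_outcomes negative-control outcome names (defaults to all
#'   `nc_*` conditions on the table).
#' @param config an [rd_config()].
#' @param alpha significance level for counting.
#' @return list with `balance` and `negative_controls` tibbles,
#'   `n_significant_at_05` and `expected_by_chance`.
#' @export
balance_and_negative_controls <- function(persons,
                                          cohort = "no_cognitive_impairment",
                                          covariates = NULL,
                                          control_outcomes = NULL,
                                          config = rd_config(),
                                          alpha = 0.05) {
  dat <- if (identical(cohort, "all")) persons else build_cohort(persons, cohort)
  if (is.null(covariates)) {
    covariates <- c(grep("^charlson_", names(dat), value = TRUE),
                    grep("_pre$", names(dat), value = TRUE))
  }
  if (is.null(control_outcomes)) {
    control_outcomes <- sub("_date$", "", grep("^nc_.*_date$", names(dat), value = TRUE))
  }
  x <- center_running_variable(dat$week_of_birth)
  run_on <- function(yvec, nm) {
    tb <- tibble::tibble(centered_wob = x, outcome = as.numeric(yvec))
    tb <- tb[!is.na(tb$centered_wob), , drop = FALSE]
    if (stats::var(tb$outcome) == 0) {
      warning(sprintf("constant column `%s` skipped", nm), call. = FALSE)
      return(NULL)
    }
    tryCatch(rd_sharp(tb, config = config),
             error = function(e) {
               warning(sprintf("test `%s` failed: %s", nm, conditionMessage(e)),
                       call. = FALSE)
               NULL
             })
  }
  bal <- lapply(covariates, function(nm) run_on(dat[[nm]], nm))
  names(bal) <- covariates
  nc <- lapply(control_outcomes, function(nm) {
    run_on(ascertain_outcome(dat, outcome_spec(nm)), nm)
  })
  names(nc) <- control_outcomes
  bal_tab <- summarize_rd_fits(bal[!vapply(bal, is.null, logical(1))])
  nc_tab <- summarize_rd_fits(nc[!vapply(nc, is.null, logical(1))])
  n_tests <- nrow(bal_tab) + nrow(nc_tab)
  n_sig <- sum(c(bal_tab$p, nc_tab$p) < alpha, na.rm = TRUE)
  list(balance = bal_tab, negative_controls = nc_tab,
       n_tests = n_tests, n_significant_at_05 = n_sig,
       expected_by_chance = alpha * n_tests)
}

# rollout cohort labels with never-eligibles mapped to the label of their
# mirror-image eligible person (for cohort fixed effects under the staggered
# index-date policy)
mirror_cohort_label <- function(date_of_birth) {
  dob <- as.Date(date_of_birth)
  lab <- as.character(assign_eligibility(dob)$cohort_label)
  nev <- lab == "never_eligible"
  if (any(nev)) {
    mirrored <- DEFAULT_THRESHOLD + (DEFAULT_THRESHOLD - dob[nev])
    mirrored <- pmin(pmax(mirrored, DOB_SPAN[1]), DOB_SPAN[2])
    lab[nev] <- as.character(assign_eligibility(mirrored)$cohort_label)
  }
  lab
}

#' Robustness grid
#'
#' Cartesian product of analysis variations: bandwidth multipliers, grace
#' periods, polynomial order, the staggered-rollout index-date adjustment
#' (with rollout-cohort fixed effects), utilization-covariate adjustment and
#' the frequent-primary-care-attender restriction. Each cell is a complete
#' sharp or fuzzy run; failing cells are marked rather than aborting the
#' grid.
#'
#' @param persons person table.
#' @param cohort cohort rule.
#' @param outcome outcome name.
#' @param estimator `"sharp"` or `"fuzzy"`.
#' @param bandwidth_multiplier,grace_period_weeks,polynomial_order,staggered,utilization_adjust,frequent_attenders
#'   grid axes (vectors; the Cartesian product is evaluated).
#' @param config base [rd_config()].
#' @return tibble with one row per grid cell.
#' @export
robustness_grid <- function(persons,
                            cohort = "no_cognitive_impairment",
                            outcome = "mci",
                            estimator = c("sharp", "fuzzy"),
                            bandwidth_multiplier = c(0.5, 0.75, 1, 1.25, 1.5, 1.75, 2),
                            grace_period_weeks = 0L,
                            polynomial_order = 1L,
                            staggered = FALSE,
                            utilization_adjust = FALSE,
                            frequent_attenders = FALSE,
                            config = rd_config()) {
  estimator <- match.arg(estimator)
  grid <- expand.grid(bandwidth_multiplier = bandwidth_multiplier,
                      grace_period_weeks = grace_period_weeks,
                      polynomial_order = polynomial_order,
                      staggered = staggered,
                      utilization_adjust = utilization_adjust,
                      frequent_attenders = frequent_attenders,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    res <- tryCatch({
      dat <- persons
      if (g$frequent_attenders) {
        pre_cols <- grep("^pc_visits_pre", names(dat), value = TRUE)
        dat <- dat[rowSums(as.matrix(dat[pre_cols]) >= 1) == length(pre_cols), ,
                   drop = FALSE]
      }
      spec <- outcome_spec(outcome, grace_period_weeks = g$grace_period_weeks,
                           index_date_policy = if (g$staggered) "own_eligibility_date" else "program_start")
      ac <- analysis_cohort(dat, cohort, spec)
      cfg <- config
      cfg$polynomial_order <- as.integer(g$polynomial_order)
      cfg$bias_order <- cfg$polynomial_order + 1L
      cfg$bandwidth_policy <- "multiplier"
      cfg$bandwidth_multiplier <- g$bandwidth_multiplier
      if (g$utilization_adjust) cfg$covariates <- c(cfg$covariates, "pc_visits_followup")
      if (g$staggered) {
        ac$rollout_cohort <- mirror_cohort_label(ac$date_of_birth)
        cfg$fixed_effects <- c(cfg$fixed_effects, "rollout_cohort")
      }
      if (estimator == "sharp") rd_sharp(ac, config = cfg) else rd_fuzzy(ac, config = cfg)
    }, error = function(e) {
      warning(sprintf("grid cell %d failed: %s", i, conditionMessage(e)), call. = FALSE)
      NULL
    })
    cell <- tibble::as_tibble(g)
    if (is.null(res)) {
      cbind(cell, tibble::tibble(estimate = NA_real_, estimate_bc = NA_real_,
                                 ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                                 h = NA_real_, status = "failed"))
    } else {
      cbind(cell, tibble::tibble(estimate = res$estimate, estimate_bc = res$estimate_bc,
                                 ci_lo = res$ci_robust[1], ci_hi = res$ci_robust[2],
                                 p = res$p_robust, h = res$bandwidth_h, status = "ok"))
    }
  })
  tibble::as_tibble(do.call(rbind, rows))
}
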
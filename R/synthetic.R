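# Synthetic linked-EHR cohort generator with potential-outcome bookkeeping.

CHARLSON_CONDITIONS <- c(
  "myocardial_infarction", "congestive_heart_failure", "peripheral_vascular_disease",
  "cerebrovascular_disease", "dementia", "copd", "rheumatic_disease",
  "peptic_ulcer_disease", "mild_liver_disease", "diabetes",
  "diabetes_complications", "hemiplegia", "renal_disease", "cancer",
  "moderate_severe_liver_disease", "metastatic_carcinoma"
)

default_comorbidity_prevalences <- function() {
  c(myocardial_infarction = 0.11, congestive_heart_failure = 0.10,
    peripheral_vascular_disease = 0.08, cerebrovascular_disease = 0.12,
    copd = 0.12, rheumatic_disease = 0.05, peptic_ulcer_disease = 0.06,
    mild_liver_disease = 0.02, diabetes = 0.20, diabetes_complications = 0.05,
    hemiplegia = 0.02, renal_disease = 0.08, cancer = 0.12,
    moderate_severe_liver_disease = 0.005, metastatic_carcinoma = 0.01)
}

default_negative_control_risk <- function() {
  c(ischemic_heart_disease = 0.08, copd = 0.06, stroke = 0.09,
    lower_respiratory_infection = 0.30, lung_cancer = 0.015, falls = 0.30,
    colorectal_cancer = 0.02, low_back_pain = 0.12, diabetes = 0.06,
    pancreatic_cancer = 0.005)
}

default_preventive_uptake <- function() {
  c(flu_vaccine = 0.686, ppv = 0.703, statin = 0.461,
    antihypertensive = 0.609, breast_screening = 0.225)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the statistical structure of the rollout natural
#' experiment that motivates the package: weekly dates of birth spanning
#' September 1925 to September 1942, a vaccination-uptake discontinuity at the
#' 1933-09-02 threshold with one-sided noncompliance (left limit 0, right
#' limit 0.459, or 0.287 for persons living with dementia at baseline), smooth
#' log-odds age trends in outcome risk, 9-year cumulative binary outcomes and
#' baseline comorbidity structure. Because the configured treatment effect
#' acts on outcomes only through simulated receipt, the true complier average
#' causal effect equals `true_itt / (uptake_right - uptake_left)` by
#' construction.
#'
#' @param n_persons number of persons to simulate.
#' @param dob_start,dob_end span of dates of birth.
#' @param threshold_date date-of-birth eligibility threshold.
#' @param uptake_right_limit uptake probability just right of the threshold
#'   (cohort without cognitive impairment).
#' @param uptake_right_limit_dementia uptake just right of the threshold among
#'   persons living with dementia at baseline.
#' @param uptake_left_limit uptake among the never eligible (0 reproduces
#'   one-sided noncompliance).
#' @param uptake_dob_slope per-week change in uptake among eligibles.
#' @param baseline_outcome_risk named probabilities of each outcome over the
#'   9-year window for a person born at the threshold.
#' @param outcome_age_trend per-week log-odds slope of outcome risk in age
#'   (smooth across the threshold); scalar or named per outcome.
#' @param quadratic_age_trend optional per-week^2 log-odds curvature.
#' @param true_itt named additive risk changes caused by eligibility, acting
#'   only through receipt.
#' @param effect_gender_ratio multiplier of the female effect relative to
#'   male, holding the population-average effect at `true_itt`.
#' @param female_share probability of female gender.
#' @param baseline_dementia_prev prevalence of dementia at baseline.
#' @param baseline_ci_extra_prev prevalence of non-dementia cognitive
#'   impairment at baseline.
#' @param comorbidity_prevalences named prevalences of the Charlson
#'   conditions (the dementia flag mirrors baseline dementia).
#' @param preperiod_risk named probabilities of pre-period (placebo) events,
#'   independent of eligibility side.
#' @param negative_control_risk named 9-year risks of negative-control
#'   conditions, independent of eligibility side.
#' @param preventive_uptake named baseline prevalences of preventive health
#'   service indicators.
#' @param dementia_type_weights multinomial weights for incident dementia
#'   type labels.
#' @param dementia_type_effect_ratio named multipliers of the receipt effect
#'   on incident dementia by (latent) type; all 1 gives equal relative
#'   effects across types.
#' @param pc_visit_rate Poisson mean of primary care visits per year.
#' @param include_unspecified_gender add one person of unspecified gender to
#'   exercise schema tolerance.
#' @param straddle_rule assignment of the threshold-straddling birth week
#'   (see [center_running_variable()]).
#' @param rng_seed integer seed; identical config and seed give an identical
#'   table.
#' @return a validated `synthetic_config` object.
#' @export
synthetic_config <- function(n_persons,
                             dob_start = as.Date("1925-09-01"),
                             dob_end = as.Date("1942-09-01"),
                             threshold_date = as.Date("1933-09-02"),
                             uptake_right_limit = 0.459,
                             uptake_right_limit_dementia = 0.287,
                             uptake_left_limit = 0,
                             uptake_dob_slope = 0,
                             baseline_outcome_risk = c(mci = 0.073, dementia = 0.150,
                                                       death_due_to_dementia = 0.491,
                                                       death_other = 0.50),
                             outcome_age_trend = 0.002,
                             quadratic_age_trend = 0,
                             true_itt = c(mci = -0.015, dementia = -0.013,
                                          death_due_to_dementia = -0.085),
                             effect_gender_ratio = 1,
                             female_share = 0.546,
                             baseline_dementia_prev = 0.04706,
                             baseline_ci_extra_prev = 0.02634,
                             comorbidity_prevalences = default_comorbidity_prevalences(),
                             preperiod_risk = c(mci = 0.04, death_due_to_dementia = 0.25),
                             negative_control_risk = default_negative_control_risk(),
                             preventive_uptake = default_preventive_uptake(),
                             dementia_type_weights = c(alzheimer = 0.45, vascular = 0.25,
                                                       mixed = 0.20, other = 0.10),
                             dementia_type_effect_ratio = c(alzheimer = 1, vascular = 1,
                                                            mixed = 1, other = 1),
                             pc_visit_rate = 2,
                             include_unspecified_gender = FALSE,
                             straddle_rule = "majority",
                             rng_seed = 1L) {
  cfg <- list(
    n_persons = check_count(n_persons, "n_persons"),
    dob_start = as_date_strict(dob_start, "dob_start"),
    dob_end = as_date_strict(dob_end, "dob_end"),
    threshold_date = as_date_strict(threshold_date, "threshold_date"),
    uptake_right_limit = check_prob(uptake_right_limit, "uptake_right_limit"),
    uptake_right_limit_dementia = check_prob(uptake_right_limit_dementia,
                                             "uptake_right_limit_dementia"),
    uptake_left_limit = check_prob(uptake_left_limit, "uptake_left_limit"),
    uptake_dob_slope = uptake_dob_slope,
    baseline_outcome_risk = check_prob(baseline_outcome_risk, "baseline_outcome_risk"),
    outcome_age_trend = outcome_age_trend,
    quadratic_age_trend = quadratic_age_trend,
    true_itt = true_itt,
    effect_gender_ratio = effect_gender_ratio,
    female_share = check_prob(female_share, "female_share"),
    baseline_dementia_prev = check_prob(baseline_dementia_prev, "baseline_dementia_prev"),
    baseline_ci_extra_prev = check_prob(baseline_ci_extra_prev, "baseline_ci_extra_prev"),
    comorbidity_prevalences = check_prob(comorbidity_prevalences, "comorbidity_prevalences"),
    preperiod_risk = check_prob(preperiod_risk, "preperiod_risk"),
    negative_control_risk = check_prob(negative_control_risk, "negative_control_risk"),
    preventive_uptake = check_prob(preventive_uptake, "preventive_uptake"),
    dementia_type_weights = dementia_type_weights,
    dementia_type_effect_ratio = dementia_type_effect_ratio,
    pc_visit_rate = pc_visit_rate,
    include_unspecified_gender = isTRUE(include_unspecified_gender),
    straddle_rule = straddle_rule,
    rng_seed = check_count(rng_seed, "rng_seed", positive = FALSE)
  )
  if (!is.numeric(cfg$uptake_dob_slope) || !is.finite(cfg$uptake_dob_slope)) {
    stop_field("uptake_dob_slope", "must be a finite number")
  }
  if (!all(is.finite(cfg$true_itt)) || any(abs(cfg$true_itt) > 1)) {
    stop_field("true_itt", "must be finite risk differences in [-1, 1]")
  }
  if (!all(is.finite(cfg$outcome_age_trend))) {
    stop_field("outcome_age_trend", "must be finite")
  }
  if (!is.finite(cfg$effect_gender_ratio) || cfg$effect_gender_ratio < 0) {
    stop_field("effect_gender_ratio", "must be a nonnegative number")
  }
  if (!(cfg$dob_start < cfg$threshold_date && cfg$threshold_date < cfg$dob_end)) {
    stop_field("threshold_date", "requires dob_start < threshold_date < dob_end")
  }
  if (!all(names(cfg$true_itt) %in% names(cfg$baseline_outcome_risk))) {
    stop_field("true_itt", "names must be a subset of baseline_outcome_risk names")
  }
  missing_charlson <- setdiff(setdiff(CHARLSON_CONDITIONS, "dementia"),
                              names(cfg$comorbidity_prevalences))
  if (length(missing_charlson)) {
    stop_field("comorbidity_prevalences",
               paste("missing conditions:", paste(missing_charlson, collapse = ", ")))
  }
  structure(cfg, class = "synthetic_config")
}

#' Read a generator configuration from YAML
#'
#' Field names mirror the arguments of [synthetic_config()].
#'
#' @param path YAML file.
#' @return a `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("baseline_outcome_risk", "true_itt", "comorbidity_prevalences",
               "preperiod_risk", "negative_control_risk", "preventive_uptake",
               "dementia_type_weights", "dementia_type_effect_ratio")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(synthetic_config, raw)
}

trend_for <- function(cfg, outcome) {
  tr <- cfg$outcome_age_trend
  if (length(tr) == 1L && is.null(names(tr))) return(unname(tr))
  if (outcome %in% names(tr)) unname(tr[[outcome]]) else 0
}

#' Generate a synthetic person-level cohort
#'
#' Simulates a linked electronic-health-record style population with a
#' vaccination-uptake discontinuity at the date-of-birth threshold and
#' configurable treatment effects that act only through receipt. Eligibility
#' is defined at week-of-birth resolution (the resolution at which linked
#' demographic registers carry dates of birth), so the sign of the centered
#' running variable and eligibility coincide exactly.
#'
#' The returned table carries a `truth` attribute with the generator's
#' potential-outcome bookkeeping: per-person compliance class, and for each
#' outcome the event probabilities and both potential outcomes, so tests can
#' verify that the realised outcome equals `Y(receipt)` and that the mean
#' complier effect matches the configured complier average causal effect.
#'
#' @param config a [synthetic_config()].
#' @return tibble of person records (one row per person).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(cfg$rng_seed)

  n <- cfg$n_persons
  span <- as.integer(cfg$dob_end - cfg$dob_start)
  dob <- cfg$dob_start + sample.int(span + 1L, n, replace = TRUE) - 1L
  wob <- week_monday(dob)
  x <- center_running_variable(wob, cfg$threshold_date, cfg$straddle_rule)
  eligible <- !is.na(x) & x >= 0L

  gender <- ifelse(stats::runif(n) < cfg$female_share, "female", "male")
  if (cfg$include_unspecified_gender && n >= 1L) gender[1L] <- "unspecified"
  female <- gender == "female"
  wimd <- sample(1:5, n, replace = TRUE,
                 prob = c(0.167, 0.190, 0.218, 0.207, 0.218))

  baseline_dementia <- stats::runif(n) < cfg$baseline_dementia_prev
  ci_extra <- stats::runif(n) < cfg$baseline_ci_extra_prev / (1 - cfg$baseline_dementia_prev)
  baseline_ci <- baseline_dementia | ci_extra

  charlson <- lapply(setdiff(CHARLSON_CONDITIONS, "dementia"), function(cond) {
    stats::runif(n) < cfg$comorbidity_prevalences[[cond]]
  })
  names(charlson) <- paste0("charlson_", setdiff(CHARLSON_CONDITIONS, "dementia"))
  charlson <- c(charlson[1:4], list(charlson_dementia = baseline_dementia), charlson[5:15])
  charlson_count <- Reduce(`+`, charlson)

  # severity proxies (dementia-related care intensity), baseline-dementia only
  n_adm <- integer(n)
  n_adm[baseline_dementia] <- stats::rpois(sum(baseline_dementia), 1.0)
  inpatient_days <- integer(n)
  has_adm <- n_adm > 0L
  inpatient_days[has_adm] <- stats::rpois(sum(has_adm), n_adm[has_adm] * 7)
  n_recordings <- integer(n)
  n_recordings[baseline_dementia] <- 1L + stats::rpois(sum(baseline_dementia), 2.5)

  # vaccination receipt: single uniform draw gives nested (one-sided monotone)
  # compliance; the configured treatment effect travels only through receipt
  xx <- x
  xx[is.na(xx)] <- 0L
  uptake_right <- ifelse(baseline_dementia, cfg$uptake_right_limit_dementia,
                         cfg$uptake_right_limit)
  u_v <- stats::runif(n)
  p_take_right <- pmin(1, pmax(0, uptake_right + cfg$uptake_dob_slope * xx))
  would_take <- u_v < p_take_right
  takes_left <- u_v < cfg$uptake_left_limit
  vaccinated <- takes_left
  vaccinated[eligible] <- would_take[eligible]

  sched <- assign_eligibility(dob)
  elig_start <- sched$eligibility_start
  elig_start[is.na(elig_start)] <- PROGRAM_START # straddle-week / never-eligible takers
  vaccination_date <- rep(as.Date(NA), n)
  vaccination_date[vaccinated] <-
    elig_start[vaccinated] + floor(stats::runif(sum(vaccinated)) * 365)

  # gender multipliers keep the population-average effect at true_itt
  r <- cfg$effect_gender_ratio
  fs <- cfg$female_share
  denom_g <- fs * r + (1 - fs)
  gmult <- ifelse(female, r / denom_g, 1 / denom_g)

  follow_days <- as.integer(add_years(PROGRAM_START, 9L) - 1L - PROGRAM_START)
  ex_charlson <- sum(cfg$comorbidity_prevalences) + cfg$baseline_dementia_prev
  severity_shift <- 0.10 * (charlson_count - ex_charlson) +
    0.05 * (n_recordings - 3.5) + 0.005 * (inpatient_days - 7)

  latent_type <- sample(names(cfg$dementia_type_weights), n, replace = TRUE,
                        prob = cfg$dementia_type_weights)

  truth <- list(person_id = sprintf("p%07d", seq_len(n)),
                complier = would_take & !takes_left,
                would_take = would_take)
  outc <- list()
  for (nm in names(cfg$baseline_outcome_risk)) {
    base <- cfg$baseline_outcome_risk[[nm]]
    lp <- stats::qlogis(base) - trend_for(cfg, nm) * xx +
      cfg$quadratic_age_trend * xx^2
    if (nm == "death_due_to_dementia") lp <- lp + severity_shift
    p0 <- stats::plogis(lp)
    jump <- (if (nm == "death_due_to_dementia") cfg$uptake_right_limit_dementia
             else cfg$uptake_right_limit) - cfg$uptake_left_limit
    itt <- if (nm %in% names(cfg$true_itt)) cfg$true_itt[[nm]] else 0
    cace <- if (itt == 0) 0 else itt / jump
    delta <- cace * gmult
    if (nm == "dementia") {
      delta <- delta * unname(cfg$dementia_type_effect_ratio[latent_type])
    }
    p1 <- pmin(1, pmax(0, p0 + delta))
    applicable <- switch(nm,
      mci = !baseline_ci,
      dementia = !baseline_dementia,
      death_due_to_dementia = baseline_dementia,
      rep(TRUE, n)
    )
    u <- stats::runif(n)
    y0 <- applicable & (u < p0)
    y1 <- applicable & (u < p1)
    y <- y0
    y[vaccinated] <- y1[vaccinated]
    date <- rep(as.Date(NA), n)
    date[y] <- PROGRAM_START + floor(stats::runif(sum(y)) * (follow_days + 1L))
    outc[[nm]] <- list(y = y, date = date)
    truth[[paste0("p0_", nm)]] <- ifelse(applicable, p0, 0)
    truth[[paste0("p1_", nm)]] <- ifelse(applicable, p1, 0)
    truth[[paste0("y0_", nm)]] <- y0
    truth[[paste0("y1_", nm)]] <- y1
  }

  # deaths: earliest of the dementia-caused and other-cause event
  other_codes <- c("I25", "C34", "J44", "I64", "C61", "N18")
  dd <- outc[["death_due_to_dementia"]]
  do <- outc[["death_other"]]
  if (is.null(dd)) dd <- list(y = rep(FALSE, n), date = as.Date(rep(NA, n)))
  if (is.null(do)) do <- list(y = rep(FALSE, n), date = as.Date(rep(NA, n)))
  death_date <- pmin(dd$date, do$date, na.rm = TRUE)
  # a dementia-caused death event always contributes the underlying cause, so
  # the ascertained dementia-death outcome coincides with the generated event
  # indicator (and with its configured risk and treatment effect)
  dem_first <- dd$y
  any_death <- dd$y | do$y
  underlying <- rep(NA_character_, n)
  underlying[any_death] <- sample(other_codes, sum(any_death), replace = TRUE)
  underlying[dem_first] <- "F03"
  contrib <- rep(NA_character_, n)
  extra_dem <- baseline_dementia & any_death & !dem_first & stats::runif(n) < 0.5
  contrib[extra_dem] <- "F03"

  mci_date <- if (!is.null(outc[["mci"]])) outc[["mci"]]$date else as.Date(rep(NA, n))
  dementia_date <- if (!is.null(outc[["dementia"]])) outc[["dementia"]]$date else as.Date(rep(NA, n))
  # clamp diagnosis records at the death date (indicator values unaffected)
  clamp <- function(d) {
    late <- !is.na(d) & !is.na(death_date) & d > death_date
    d[late] <- death_date[late]
    d
  }
  mci_date <- clamp(mci_date)
  dementia_date <- clamp(dementia_date)
  has_dem <- !is.na(dementia_date)
  dementia_type <- rep(NA_character_, n)
  dementia_type[has_dem] <- latent_type[has_dem]

  # pre-period events: independent of eligibility side by construction
  pre_span <- as.integer(PROGRAM_START - 1L - add_years(PROGRAM_START, -9L))
  pre_cols <- list()
  pre_start <- add_years(PROGRAM_START, -9L)
  for (nm in names(cfg$preperiod_risk)) {
    hit <- stats::runif(n) < cfg$preperiod_risk[[nm]]
    d <- rep(as.Date(NA), n)
    d[hit] <- pre_start + floor(stats::runif(sum(hit)) * (pre_span + 1L))
    pre_cols[[paste0("pre_", nm, "_date")]] <- d
  }

  nc_cols <- list()
  for (nm in names(cfg$negative_control_risk)) {
    hit <- stats::runif(n) < cfg$negative_control_risk[[nm]]
    d <- rep(as.Date(NA), n)
    d[hit] <- PROGRAM_START + floor(stats::runif(sum(hit)) * (follow_days + 1L))
    nc_cols[[paste0("nc_", nm, "_date")]] <- d
  }

  prev_cols <- list()
  for (nm in names(cfg$preventive_uptake)) {
    p <- cfg$preventive_uptake[[nm]]
    v <- stats::runif(n) < p
    if (nm == "breast_screening") v <- v & female
    prev_cols[[paste0(nm, "_pre")]] <- v
  }

  pc <- matrix(stats::rpois(5L * n, cfg$pc_visit_rate), nrow = n)
  colnames(pc) <- paste0("pc_visits_pre", 1:5)
  pc_follow <- stats::rpois(n, cfg$pc_visit_rate * 9)

  persons <- tibble::as_tibble(c(
    list(person_id = truth$person_id,
         date_of_birth = dob,
         week_of_birth = wob,
         gender = gender,
         wimd_quintile = wimd),
    charlson,
    list(baseline_cognitive_impairment = baseline_ci,
         baseline_dementia = baseline_dementia,
         vaccination_date = vaccination_date,
         mci_date = mci_date,
         dementia_date = dementia_date,
         dementia_type = dementia_type,
         death_date = death_date,
         underlying_cause = underlying,
         contributing_causes = contrib),
    pre_cols,
    nc_cols,
    prev_cols,
    as.data.frame(pc),
    list(pc_visits_followup = pc_follow,
         inpatient_days_dementia = as.integer(inpatient_days),
         n_dementia_admissions = as.integer(n_adm),
         n_dementia_recordings = as.integer(n_recordings))
  ))
  attr(persons, "truth") <- tibble::as_tibble(truth)
  attr(persons, "config") <- cfg
  persons
}

#' Write / read a person table as CSV
#'
#' The round trip is lossless: ISO-8601 dates, absent dates encoded as empty
#' fields, column order preserved.
#'
#' @param persons person table.
#' @param path CSV file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns the
#'   person tibble.
#' @export
write_cohort <- function(persons, path) {
  out <- as.data.frame(persons)
  for (nm in names(out)) {
    if (inherits(out[[nm]], "Date")) out[[nm]] <- format(out[[nm]], "%Y-%m-%d")
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         colClasses = "character")
  mandatory <- c("person_id", "date_of_birth", "week_of_birth", "gender")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing)) {
    stop(paste("cohort file lacks mandatory column(s):", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  date_cols <- grep("(_date$|^date_of_birth$|^week_of_birth$)", names(raw), value = TRUE)
  logical_cols <- intersect(
    c(grep("^charlson_", names(raw), value = TRUE),
      "baseline_cognitive_impairment", "baseline_dementia",
      grep("_pre$", names(raw), value = TRUE)),
    names(raw)
  )
  int_cols <- intersect(
    c("wimd_quintile", grep("^pc_visits", names(raw), value = TRUE),
      "inpatient_days_dementia", "n_dementia_admissions", "n_dementia_recordings"),
    names(raw)
  )
  for (nm in date_cols) {
    d <- as.Date(raw[[nm]], format = "%Y-%m-%d")
    if (any(is.na(d) & !is.na(raw[[nm]]))) {
      stop(sprintf("unparseable dates in column `%s`", nm), call. = FALSE)
    }
    raw[[nm]] <- d
  }
  for (nm in logical_cols) raw[[nm]] <- as.logical(raw[[nm]])
  for (nm in int_cols) raw[[nm]] <- as.integer(raw[[nm]])
  tibble::as_tibble(raw)
}
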
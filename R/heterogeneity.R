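# Effect heterogeneity: gender-interaction IV, severity-score subgroups,
# delta-method relative effects, dementia-type contrasts.

#' Gender-interaction fuzzy regression discontinuity
#'
#' Two-instrument two-stage least squares in which receipt and its
#' interaction with male gender are instrumented by eligibility and its male
#' interaction, with fully gender-interacted running-variable terms,
#' triangular kernel weights and the MSE-optimal bandwidth of the
#' corresponding specification without interaction terms. The interaction
#' coefficient identifies the male-minus-female difference in the effect of
#' receipt; per-gender effects are recovered as linear combinations and agree
#' exactly with separate single-gender fits at the same bandwidth.
#' Interaction inference uses the robust (not bias-corrected) covariance.
#'
#' @param data analysis cohort with `male`, `eligible`, `vaccinated`.
#' @param outcome outcome column.
#' @param config an [rd_config()].
#' @param running running-variable column.
#' @return list with the interaction estimate (`beta4`), per-gender complier
#'   effects, and the bandwidth used.
#' @export
rd_gender_interaction <- function(data, outcome = "outcome", config = rd_config(),
                                  running = "centered_wob") {
  bw <- resolve_bandwidths(data, outcome, config, running)
  x <- as.numeric(data[[running]])
  use <- !is.na(x) & abs(x) <= bw$h
  x <- x[use]
  y <- as.numeric(data[[outcome]])[use]
  v <- as.numeric(data[["vaccinated"]])[use]
  male <- as.numeric(data[["male"]])[use]
  d <- as.numeric(x >= 0)
  k <- kernel_weight(x / bw$h)
  for (side in c(0, 1)) {
    for (g in c(0, 1)) {
      if (!any(d == side & male == g & k > 0)) {
        stop("both genders must be present on both sides within the bandwidth",
             call. = FALSE)
      }
    }
  }
  p <- config$polynomial_order
  poly_terms <- function(base) {
    out <- NULL
    for (j in seq_len(p)) out <- cbind(out, base * x^j, base * d * x^j)
    out
  }
  base_X <- cbind(1, poly_terms(1), male, poly_terms(male))
  X <- cbind(base_X, receipt = v, receipt_male = v * male)
  Z <- cbind(base_X, inst = d, inst_male = d * male)
  fit <- tsls_fit(y, X, Z, w = k,
                  cluster = if (config$variance_estimator == "cluster_by_week") x else NULL)
  b1 <- fit$coef["receipt"]
  b4 <- fit$coef["receipt_male"]
  vc <- fit$vcov
  se4 <- sqrt(vc["receipt_male", "receipt_male"])
  se_f <- sqrt(vc["receipt", "receipt"])
  se_m <- sqrt(vc["receipt", "receipt"] + vc["receipt_male", "receipt_male"] +
                 2 * vc["receipt", "receipt_male"])
  z <- stats::qnorm(1 - config$alpha / 2)
  list(
    beta4 = unname(b4), se = unname(se4),
    p = unname(2 * stats::pnorm(-abs(b4 / se4))),
    female = list(estimate = unname(b1), se = unname(se_f),
                  ci = unname(c(b1 - z * se_f, b1 + z * se_f))),
    male = list(estimate = unname(b1 + b4), se = unname(se_m),
                ci = unname(c(b1 + b4 - z * se_m, b1 + b4 + z * se_m))),
    bandwidth_h = bw$h, n_eff = length(y)
  )
}

#' Fit a severity (mortality-risk) score on ineligible persons
#'
#' Logistic model of a nine-year death outcome on age at program start and
#' the Charlson comorbidity conditions (AIDS is never among the predictors;
#' the condition catalogue used here excludes it), optionally augmented with
#' dementia-related care-intensity counts. Coefficients are estimated on
#' ineligible persons only, so the score is untouched by the treatment;
#' predictions impute a fixed age of 80 years so that the score never reads
#' a person's true age.
#'
#' @param persons person table (typically the cohort living with dementia at
#'   baseline).
#' @param outcome `"death_all_cause"` or `"death_due_to_dementia"`.
#' @param include_dementia_care add inpatient days and diagnosis-recording
#'   counts as predictors (used for the predicted dementia-death risk).
#' @param threshold_date eligibility threshold defining the ineligible side.
#' @param straddle_rule see [center_running_variable()].
#' @param ridge_lambda ridge penalty used in the penalised refit when the
#'   unpenalised likelihood is separated.
#' @return a `severity_model` with named coefficients and `imputed_age = 80`.
#' @export
fit_severity_model <- function(persons,
                               outcome = "death_all_cause",
                               include_dementia_care = identical(outcome, "death_due_to_dementia"),
                               threshold_date = DEFAULT_THRESHOLD,
                               straddle_rule = "majority",
                               ridge_lambda = 1e-2) {
  x <- center_running_variable(persons$week_of_birth, threshold_date, straddle_rule)
  train <- persons[!is.na(x) & x < 0, , drop = FALSE]
  y <- ascertain_outcome(train, outcome_spec(outcome))
  preds <- build_severity_design(train, include_dementia_care)
  keep <- apply(preds$X, 2, function(col) stats::var(col) > 0)
  X <- preds$X[, keep, drop = FALSE]
  fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y, family = stats::binomial()))
  separated <- !fit$converged || any(abs(fit$coefficients) > 15)
  if (separated) {
    warning("separation in severity model; refitting with a small ridge penalty",
            call. = FALSE)
    gfit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                           lambda = ridge_lambda, standardize = FALSE)
    coefs <- stats::setNames(
      c(as.numeric(gfit$a0), as.numeric(gfit$beta)),
      c("(Intercept)", rownames(gfit$beta))
    )
  } else {
    coefs <- stats::setNames(fit$coefficients, c("(Intercept)", colnames(X)))
  }
  structure(list(
    coefficients = coefs,
    predictor_names = colnames(X),
    include_dementia_care = include_dementia_care,
    imputed_age = 80,
    outcome = outcome,
    training_side = "ineligible_only",
    n_train = length(y)
  ), class = "severity_model")
}

build_severity_design <- function(persons, include_dementia_care) {
  age <- as.numeric(PROGRAM_START - as.Date(persons$date_of_birth)) / 365.25
  charlson_cols <- grep("^charlson_", names(persons), value = TRUE)
  X <- cbind(age = age,
             as.matrix(data.frame(lapply(persons[charlson_cols], as.numeric))))
  if (include_dementia_care) {
    X <- cbind(X,
               inpatient_days_dementia = as.numeric(persons$inpatient_days_dementia),
               n_dementia_recordings = as.numeric(persons$n_dementia_recordings))
  }
  list(X = X)
}

#' Score persons with a severity model
#'
#' @param persons person table.
#' @param model a [fit_severity_model()] object.
#' @return numeric predicted probabilities, with age imputed at 80 years.
#' @export
predict_severity <- function(persons, model) {
  X <- build_severity_design(persons, model$include_dementia_care)$X
  X[, "age"] <- model$imputed_age
  keep <- intersect(colnames(X), model$predictor_names)
  lp <- model$coefficients["(Intercept)"] +
    drop(X[, keep, drop = FALSE] %*% model$coefficients[keep])
  stats::plogis(lp)
}

#' Median-split subgroup labels from a severity score
#'
#' The median is computed on the full scored cohort; ties at the median are
#' assigned to the below-median group.
#'
#' @param persons person table.
#' @param model a severity model, or a numeric score vector.
#' @return factor with levels `below_median`, `above_median`.
#' @export
score_and_split <- function(persons, model) {
  score <- if (is.numeric(model)) model else predict_severity(persons, model)
  med <- stats::median(score)
  if (all(score == score[1])) {
    warning("degenerate severity split: all scores identical", call. = FALSE)
  }
  factor(ifelse(score <= med, "below_median", "above_median"),
         levels = c("below_median", "above_median"))
}

#' Dementia severity measures
#'
#' Five per-person severity indicators measured before program start: the
#' count measures (total inpatient days in dementia-related admissions,
#' number of such admissions, number of recorded dementia diagnoses) and the
#' two model-based predicted risks (death due to dementia; death from any
#' cause), when the fitted models are supplied.
#'
#' @param persons person table.
#' @param model_death_dementia,model_death_all optional severity models.
#' @return tibble of measures, one row per person.
#' @export
severity_measures <- function(persons, model_death_dementia = NULL,
                              model_death_all = NULL) {
  counts <- persons[c("inpatient_days_dementia", "n_dementia_admissions",
                      "n_dementia_recordings")]
  if (any(unlist(counts) < 0)) stop("negative severity counts", call. = FALSE)
  out <- tibble::as_tibble(counts)
  if (!is.null(model_death_dementia)) {
    out$predicted_death_dementia <- predict_severity(persons, model_death_dementia)
  }
  if (!is.null(model_death_all)) {
    out$predicted_death_all_cause <- predict_severity(persons, model_death_all)
  }
  out
}

#' Relative effect with delta-method inference
#'
#' Divides the absolute threshold effect by the predicted outcome level just
#' left of the threshold: for the eligibility effect the denominator is the
#' left intercept of the intent-to-treat fit; for the receipt effect it is
#' the untreated-complier left limit, computed under one-sided noncompliance
#' as (left limit of Y minus right limit of Y(1-V)) divided by the
#' first-stage jump. The confidence interval propagates the full covariance
#' of numerator and denominator (influence functions clustered by week).
#' Conventional (not bias-corrected) components are used for both.
#'
#' @param rd an `rd_result` from [rd_sharp()] (eligibility) or [rd_fuzzy()]
#'   (receipt).
#' @param estimand `"eligibility"` or `"receipt"`.
#' @param denominator_guard error when the denominator is closer to zero.
#' @return a `relative_effect` list with `relative_estimate`, `ci`, `p`.
#' @export
relative_effect <- function(rd, estimand = c("eligibility", "receipt"),
                            denominator_guard = 1e-3) {
  estimand <- match.arg(estimand)
  stopifnot(inherits(rd, "rd_result"))
  cfg <- rd$config
  cl_type <- cfg$variance_estimator
  z <- stats::qnorm(1 - cfg$alpha / 2)
  if (estimand == "eligibility") {
    if (rd$kind != "sharp") stop("eligibility relative effect needs a sharp fit", call. = FALSE)
    fit <- rd$internals$fit
    x <- rd$internals$x
    num <- fit$tau_conv
    den <- fit$left_limit
    psi_num <- fit$w_conv * fit$r_conv
    psi_den <- fit$w_left_conv * fit$r_conv
  } else {
    if (rd$kind != "fuzzy") stop("receipt relative effect needs a fuzzy fit", call. = FALSE)
    x <- rd$internals$x
    yv <- rd$internals$y
    v <- rd$internals$v
    fy <- rd$internals$fit_y
    fv <- rd$internals$fit_v
    fs <- fv$tau_conv
    num <- fy$tau_conv / fs
    zout <- yv * (1 - v) # outcome among non-recipients
    fz <- rd_engine(x, zout, rd$bandwidth_h, rd$bandwidth_b,
                    cfg$polynomial_order, cfg$bias_order, cl_type, cfg$alpha)
    den <- (fy$left_limit - fz$right_limit) / fs
    psi_fs <- fv$w_conv * fv$r_conv
    psi_num <- (fy$w_conv * fy$r_conv - num * psi_fs) / fs
    psi_den <- (fy$w_left_conv * fy$r_conv - fz$w_right_conv * fz$r_conv) / fs -
      (den / fs) * psi_fs
  }
  if (abs(den) < denominator_guard) {
    stop(sprintf("relative effect undefined: denominator %.5f within guard %.0e",
                 den, denominator_guard), call. = FALSE)
  }
  psi <- psi_num / den - (num / den^2) * psi_den
  se <- sqrt(cluster_sum2(psi, x, cl_type))
  rel <- num / den
  structure(list(
    absolute_effect = num,
    denominator_left_limit = den,
    relative_estimate = rel,
    se = se,
    ci = c(rel - z * se, rel + z * se),
    p = 2 * stats::pnorm(-abs(rel / se)),
    estimand = estimand
  ), class = "relative_effect")
}

#' Relative effects on dementia diagnoses by type
#'
#' Point estimates of the relative reduction in type-specific dementia
#' incidence, by default among women (where the heterogeneity analyses locate
#' the effect) and for the three most common types. No confidence intervals
#' are produced: there is no established interval method for relative effects
#' in this design, so only point estimates are comparable across types.
#'
#' @param persons person table.
#' @param types dementia types to compare.
#' @param cohort cohort rule.
#' @param gender restrict to this gender (`NULL` for all).
#' @param estimand `"receipt"` or `"eligibility"`.
#' @param config an [rd_config()].
#' @return tibble of per-type absolute and relative point estimates.
#' @export
dementia_type_relative_effects <- function(persons,
                                           types = c("alzheimer", "vascular", "mixed"),
                                           cohort = "no_cognitive_impairment",
                                           gender = "female",
                                           estimand = c("receipt", "eligibility"),
                                           config = rd_config()) {
  estimand <- match.arg(estimand)
  if (!is.null(gender)) persons <- persons[persons$gender %in% gender, , drop = FALSE]
  rows <- lapply(types, function(tp) {
    nm <- paste0("dementia_", tp)
    ac <- analysis_cohort(persons, cohort, nm)
    if (sum(ac$outcome) == 0) {
      warning(sprintf("type %s has zero incidence; omitted", tp), call. = FALSE)
      return(NULL)
    }
    fit <- if (estimand == "receipt") rd_fuzzy(ac, config = config) else rd_sharp(ac, config = config)
    rel <- relative_effect(fit, estimand)
    tibble::tibble(type = tp,
                   absolute = rel$absolute_effect,
                   denominator = rel$denominator_left_limit,
                   relative = rel$relative_estimate)
  })
  do.call(rbind, rows)
}
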
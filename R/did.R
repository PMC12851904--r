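# Birth-season difference-in-differences estimator and its validity pretest.
#
# Eligibility for the rollout differed between the pre-September and
# post-September birth seasons only in the 1933/34 yearly birth cohort, so a
# season-by-cohort contrast identifies the effect while absorbing any
# systematic birth-season differences through month and cohort fixed effects.

DID_SPAN <- as.Date(c("1926-03-01", "1934-02-28"))

#' Build the birth-season difference-in-differences frame
#'
#' Restricts to persons born 1926-03-01 to 1934-02-28, labels yearly birth
#' cohorts centred on September 1 (`1926/27` .. `1933/34`), and splits each
#' cohort into a pre-September season (born March 1 to August 31) and a
#' post-September season (September 1 to February 28 of the succeeding year;
#' February 29 births fall in the post season by these date ranges).
#'
#' @param persons person table.
#' @param outcome an [outcome_spec()] or outcome name.
#' @param cohort cohort rule passed to [build_cohort()], or `"all"`.
#' @param code_sets cause-of-death code sets.
#' @return tibble with `person_id`, `season`, `yearly_cohort`, `birth_month`,
#'   `outcome`, `receipt`.
#' @export
build_did_frame <- function(persons, outcome = "death_due_to_dementia",
                            cohort = "living_with_dementia",
                            code_sets = default_code_sets()) {
  dat <- if (identical(cohort, "all")) persons else build_cohort(persons, cohort)
  dob <- as.Date(dat$date_of_birth)
  keep <- dob >= DID_SPAN[1] & dob <= DID_SPAN[2]
  n_dropped <- sum(!keep)
  if (n_dropped) message(sprintf("build_did_frame: %d person(s) outside the birth-date restriction excluded", n_dropped))
  dat <- dat[keep, , drop = FALSE]
  dob <- dob[keep]
  lt <- as.POSIXlt(dob)
  month <- lt$mon + 1L
  year <- lt$year + 1900L
  season <- ifelse(month >= 3L & month <= 8L, "pre_september", "post_september")
  cohort_year <- ifelse(month >= 3L, year, year - 1L)
  spec <- if (is.character(outcome)) outcome_spec(outcome) else outcome
  tibble::tibble(
    person_id = dat$person_id,
    season = factor(season, levels = c("pre_september", "post_september")),
    yearly_cohort = factor(sprintf("%d/%02d", cohort_year, (cohort_year + 1L) %% 100L)),
    birth_month = month,
    outcome = ascertain_outcome(dat, spec, code_sets),
    receipt = !is.na(dat$vaccination_date)
  )
}

#' Parallel-trends pretest: between-season gaps by yearly cohort
#'
#' Estimates the post-minus-pre season difference in the outcome for every
#' yearly birth cohort relative to the 1932/33 reference cohort, with birth
#' month and cohort fixed effects. Under the identifying assumption, all gaps
#' except possibly the 1933/34 one are zero; a significant gap in any other
#' cohort is the go/no-go signal against using the design for that outcome.
#'
#' @param frame a [build_did_frame()] table.
#' @param reference reference cohort label.
#' @param alpha significance level for the violation flag.
#' @return list with `gaps` (tibble of per-cohort estimates) and
#'   `assumption_violated` (any non-1933/34 gap significant at `alpha`).
#' @export
did_pretrend_test <- function(frame, reference = "1932/33", alpha = 0.05) {
  if (nlevels(droplevels(frame$yearly_cohort)) < 2L) {
    stop("need at least two yearly cohorts", call. = FALSE)
  }
  if (!reference %in% frame$yearly_cohort) {
    stop(sprintf("reference cohort %s absent from frame", reference), call. = FALSE)
  }
  cohorts <- setdiff(levels(droplevels(frame$yearly_cohort)), reference)
  post <- as.numeric(frame$season == "post_september")
  D <- sapply(cohorts, function(h) post * (frame$yearly_cohort == h))
  colnames(D) <- paste0("gap_", cohorts)
  df <- data.frame(outcome = frame$outcome, D,
                   month = factor(frame$birth_month),
                   cohort = droplevels(frame$yearly_cohort), check.names = FALSE)
  fit <- stats::lm(outcome ~ ., data = df)
  ct <- lmtest::coeftest(fit, vcov. = sandwich::vcovHC(fit, type = "HC1"))
  idx <- grep("^`?gap_", rownames(ct))
  gaps <- tibble::tibble(
    cohort = sub("^`?gap_([0-9/]+)`?.*$", "\\1", rownames(ct)[idx]),
    estimate = ct[idx, 1],
    se = ct[idx, 2],
    ci_lo = ct[idx, 1] - stats::qnorm(1 - alpha / 2) * ct[idx, 2],
    ci_hi = ct[idx, 1] + stats::qnorm(1 - alpha / 2) * ct[idx, 2],
    p = ct[idx, 4]
  )
  untreated <- gaps$cohort != "1933/34"
  list(gaps = gaps,
       assumption_violated = any(gaps$p[untreated] < alpha),
       alpha = alpha)
}

# weighted two-stage least squares with heteroskedasticity/cluster-robust
# sandwich covariance (CR0 with a G/(G-1) correction when clustered)
tsls_fit <- function(y, X, Z, w = NULL, cluster = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  ZtZ <- crossprod(Z, w * Z)
  Xhat <- Z %*% solve(ZtZ, crossprod(Z, w * X))
  XtX <- crossprod(Xhat, w * X)
  beta <- solve(XtX, crossprod(Xhat, w * y))
  resid <- c(y - X %*% beta)
  A <- solve(XtX)
  psi <- (w * resid) * Xhat
  if (is.null(cluster)) {
    meat <- crossprod(psi)
  } else {
    sums <- rowsum(psi, cluster)
    g <- nrow(sums)
    meat <- crossprod(sums) * if (g > 1) g / (g - 1) else 1
  }
  V <- A %*% meat %*% t(A)
  dimnames(V) <- list(colnames(X), colnames(X))
  list(coef = stats::setNames(c(beta), colnames(X)), vcov = V, residuals = resid)
}

#' Birth-season difference-in-differences, two-stage least squares
#'
#' First stage: receipt on the season-by-1933/34 interaction with month and
#' cohort fixed effects (the uptake change caused by the eligibility rule).
#' Second stage: outcome on instrumented receipt with the same fixed effects.
#' The reduced-form/first-stage ratio identity holds exactly because both
#' stages share one design.
#'
#' @param frame a [build_did_frame()] table.
#' @param alpha level for confidence intervals.
#' @param min_first_stage_F minimal first-stage F statistic (squared t) below
#'   which estimation aborts with a weak-instrument error.
#' @return a `did_result` list with first-stage, reduced-form and 2SLS
#'   estimates.
#' @export
did_2sls <- function(frame, alpha = 0.05, min_first_stage_F = 10) {
  post <- as.numeric(frame$season == "post_september")
  treat_cohort <- as.numeric(frame$yearly_cohort == "1933/34")
  if (!any(treat_cohort == 1)) stop("frame lacks the 1933/34 cohort", call. = FALSE)
  sc <- post * treat_cohort
  month_f <- factor(frame$birth_month)
  cohort_f <- droplevels(frame$yearly_cohort)
  exo <- stats::model.matrix(~ month_f + cohort_f)
  y <- as.numeric(frame$outcome)
  v <- as.numeric(frame$receipt)
  Z <- cbind(exo, instrument = sc)
  # first stage and reduced form are OLS on the instrument design
  fs <- tsls_fit(v, Z, Z)
  rf <- tsls_fit(y, Z, Z)
  g <- fs$coef["instrument"]
  g_se <- sqrt(fs$vcov["instrument", "instrument"])
  f_stat <- if (g_se > 0) (g / g_se)^2 else if (g == 0) 0 else Inf
  if (f_stat < min_first_stage_F) {
    stop(sprintf("weak first stage: F = %.2f below %.1f", f_stat,
                 min_first_stage_F), call. = FALSE)
  }
  X <- cbind(exo, receipt = v)
  iv <- tsls_fit(y, X, Z)
  b <- iv$coef["receipt"]
  b_se <- sqrt(iv$vcov["receipt", "receipt"])
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(
    first_stage_gamma = unname(g),
    first_stage_se = unname(g_se),
    reduced_form = unname(rf$coef["instrument"]),
    reduced_form_se = unname(sqrt(rf$vcov["instrument", "instrument"])),
    beta_2sls = unname(b),
    se = unname(b_se),
    ci = unname(c(b - z * b_se, b + z * b_se)),
    p = unname(2 * stats::pnorm(-abs(b / b_se))),
    n = length(y),
    alpha = alpha
  ), class = "did_result")
}

#' @export
print.did_result <- function(x, ...) {
  cat("birth-season difference-in-differences (2SLS)\n")
  cat(sprintf("  first-stage uptake gap: %.4f (SE %.4f)\n",
              x$first_stage_gamma, x$first_stage_se))
  cat(sprintf("  reduced form:           %+.4f (SE %.4f)\n",
              x$reduced_form, x$reduced_form_se))
  cat(sprintf("  effect of receipt:      %+.4f  %d%% CI [%+.4f, %+.4f]  p = %.4f\n",
              x$beta_2sls, round(100 * (1 - x$alpha)), x$ci[1], x$ci[2], x$p))
  invisible(x)
}
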
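# Fixture builders shared across test files.

# minimal person rows with every schema column, overridable per test
make_persons <- function(n = 1, ...) {
  base <- tibble::tibble(
    person_id = sprintf("t%03d", seq_len(n)),
    date_of_birth = rep(as.Date("1933-10-02"), n),
    week_of_birth = rep(as.Date("1933-10-02"), n),
    gender = rep("female", n),
    wimd_quintile = rep(3L, n),
    baseline_cognitive_impairment = rep(FALSE, n),
    baseline_dementia = rep(FALSE, n),
    vaccination_date = rep(as.Date(NA), n),
    mci_date = rep(as.Date(NA), n),
    dementia_date = rep(as.Date(NA), n),
    dementia_type = rep(NA_character_, n),
    death_date = rep(as.Date(NA), n),
    underlying_cause = rep(NA_character_, n),
    contributing_causes = rep(NA_character_, n),
    pre_mci_date = rep(as.Date(NA), n),
    pre_death_due_to_dementia_date = rep(as.Date(NA), n),
    inpatient_days_dementia = rep(0L, n),
    n_dementia_admissions = rep(0L, n),
    n_dementia_recordings = rep(0L, n)
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# small generated cohort cached per seed/size to keep the suite fast
cohort_cache <- new.env(parent = emptyenv())
gen_cohort <- function(n, seed = 1L, ...) {
  key <- paste0(n, "_", seed, "_", paste(names(list(...)), collapse = ""))
  if (is.null(cohort_cache[[key]])) {
    cohort_cache[[key]] <- generate_cohort(synthetic_config(n_persons = n,
                                                            rng_seed = seed, ...))
  }
  cohort_cache[[key]]
}

# independent closed-form weighted least squares for the sharp RD oracle:
# one joint regression with an eligibility jump and side-specific slopes
wls_oracle <- function(x, y, h, p = 1) {
  k <- pmax(0, 1 - abs(x) / h)
  d <- as.numeric(x >= 0)
  X <- cbind(1, d)
  for (j in seq_len(p)) X <- cbind(X, x^j, d * x^j)
  beta <- solve(t(X) %*% (k * X), t(X) %*% (k * y))
  list(jump = beta[2], left_intercept = beta[1])
}
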
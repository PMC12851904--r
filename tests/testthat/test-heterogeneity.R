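test_that("interaction model reproduces separate single-gender fits exactly", {
  ppl <- gen_cohort(20000, seed = 23)
  ac <- analysis_cohort(ppl, "no_cognitive_impairment", "mci")
  cfg <- rd_config(bandwidth_policy = "fixed", bandwidth = 150,
                   bias_bandwidth_policy = "same_as_h")
  gi <- rd_gender_interaction(ac, config = cfg)
  fem <- rd_fuzzy(ac[ac$gender == "female", ], config = cfg)
  mal <- rd_fuzzy(ac[ac$gender == "male", ], config = cfg)
  expect_equal(gi$female$estimate, fem$estimate, tolerance = 1e-8)
  expect_equal(gi$male$estimate, mal$estimate, tolerance = 1e-8)
  expect_equal(gi$beta4, mal$estimate - fem$estimate, tolerance = 1e-8)
})

test_that("gender interaction is null when effects are homogeneous and recovers a female-only effect", {
  ppl <- gen_cohort(40000, seed = 24)
  ac <- analysis_cohort(ppl, "no_cognitive_impairment", "mci")
  gi <- rd_gender_interaction(ac)
  expect_lt(abs(gi$beta4), 4 * gi$se)

  # female complier effect -0.051, male effect ~0
  itt <- -0.051 * 0.459 * 0.546
  cfg <- synthetic_config(60000, rng_seed = 25, true_itt = c(mci = itt),
                          effect_gender_ratio = 1e6)
  ac2 <- analysis_cohort(generate_cohort(cfg), "no_cognitive_impairment", "mci")
  gi2 <- rd_gender_interaction(ac2)
  expect_lt(abs(gi2$beta4 - 0.051), 3 * gi2$se)
  expect_lt(abs(gi2$female$estimate + 0.051), 3 * gi2$female$se)
  expect_lt(abs(gi2$male$estimate), 3 * gi2$male$se)

  expect_error(rd_gender_interaction(ac2[ac2$gender == "female", ]),
               "both genders")
})

test_that("severity scores ignore true age and respond to the configured signal", {
  two <- make_persons(2, date_of_birth = as.Date(c("1934-06-01", "1927-06-01")),
                      baseline_dementia = TRUE,
                      baseline_cognitive_impairment = TRUE,
                      n_dementia_recordings = 4L)
  for (nm in grep("^charlson_", names(gen_cohort(100, seed = 1)), value = TRUE)) {
    two[[nm]] <- c(TRUE, TRUE)
  }
  cfg <- synthetic_config(60000, rng_seed = 26, baseline_dementia_prev = 0.5,
                          baseline_ci_extra_prev = 0.01)
  dem <- build_cohort(generate_cohort(cfg), "living_with_dementia")
  model <- fit_severity_model(dem, "death_due_to_dementia",
                              include_dementia_care = TRUE)
  # identical records differing only in age score identically (age imputed 80)
  sc <- predict_severity(two, model)
  expect_equal(sc[1], sc[2], tolerance = 1e-12)
  # recovery of the generator's severity signal: +0.10 log-odds per Charlson
  # condition and +0.05 per dementia recording
  ch <- model$coefficients[grep("^charlson_", names(model$coefficients))]
  ch <- ch[names(ch) != "charlson_dementia"] # constant within the cohort, dropped
  expect_equal(unname(mean(ch)), 0.10, tolerance = 0.35)
  expect_equal(unname(model$coefficients["n_dementia_recordings"]), 0.05,
               tolerance = 0.5)
  # age coefficient reflects the per-week log-odds trend (about 0.104/year)
  expect_equal(unname(model$coefficients["age"]), 0.002 * 365.25 / 7,
               tolerance = 0.5)

  grp <- score_and_split(dem, model)
  expect_true(all(levels(grp) == c("below_median", "above_median")))
  # ties at the median fall below: the below group is never the smaller one
  expect_gte(sum(grp == "below_median"), sum(grp == "above_median"))
  # median split is invariant to strictly monotone transforms of the score
  sc_all <- predict_severity(dem, model)
  expect_identical(score_and_split(dem, model),
                   score_and_split(dem, stats::qlogis(sc_all)))

  flat <- make_persons(6, baseline_dementia = TRUE,
                       baseline_cognitive_impairment = TRUE)
  for (nm in grep("^charlson_", names(dem), value = TRUE)) flat[[nm]] <- FALSE
  expect_warning(score_and_split(flat, model), "degenerate severity split")
})

test_that("severity measures extract counts and model scores consistently", {
  p <- make_persons(2,
                    inpatient_days_dementia = c(0L, 13L),
                    n_dementia_admissions = c(0L, 3L),
                    n_dementia_recordings = c(0L, 5L))
  m <- severity_measures(p)
  expect_equal(m$inpatient_days_dementia, c(0L, 13L))
  expect_equal(m$n_dementia_admissions, c(0L, 3L))
  p_bad <- make_persons(1, inpatient_days_dementia = -1L)
  expect_error(severity_measures(p_bad), "negative")
})

test_that("relative effects are scale-invariant and reduce correctly under full compliance", {
  ppl <- gen_cohort(30000, seed = 27)
  ac <- analysis_cohort(ppl, "no_cognitive_impairment", "mci")
  cfg <- rd_config(bandwidth_policy = "fixed", bandwidth = 150,
                   bias_bandwidth_policy = "same_as_h")
  fit <- rd_sharp(ac, config = cfg)
  rel <- relative_effect(fit, "eligibility")
  expect_equal(rel$relative_estimate,
               rel$absolute_effect / rel$denominator_left_limit, tolerance = 1e-12)
  # doubling the outcome scale doubles numerator and denominator alike
  ac2 <- ac
  ac2$outcome <- 2 * ac2$outcome
  rel2 <- relative_effect(rd_sharp(ac2, config = cfg), "eligibility")
  expect_equal(rel2$relative_estimate, rel$relative_estimate, tolerance = 1e-10)
  expect_equal(rel2$se, rel$se, tolerance = 1e-10)

  # sharp compliance: the untreated-complier denominator equals the plain
  # left limit of the intent-to-treat fit
  cfgf <- synthetic_config(20000, rng_seed = 28, uptake_right_limit = 1,
                           uptake_right_limit_dementia = 1)
  acf <- analysis_cohort(generate_cohort(cfgf), "no_cognitive_impairment", "mci")
  rel_r <- relative_effect(rd_fuzzy(acf, config = cfg), "receipt")
  rel_e <- relative_effect(rd_sharp(acf, config = cfg), "eligibility")
  expect_equal(rel_r$denominator_left_limit, rel_e$denominator_left_limit,
               tolerance = 1e-10)

  # denominator guard
  ac0 <- ac
  ac0$outcome <- 0 * ac0$outcome
  expect_error(relative_effect(rd_sharp(ac0, config = cfg), "eligibility"),
               "denominator")
})

test_that("delta-method relative-effect interval matches a bootstrap", {
  cfg <- synthetic_config(6000, rng_seed = 29, true_itt = c(mci = -0.03),
                          baseline_outcome_risk = c(mci = 0.15))
  ppl <- generate_cohort(cfg)
  ac <- analysis_cohort(ppl, "no_cognitive_impairment", "mci")
  rcfg <- rd_config(bandwidth_policy = "fixed", bandwidth = 200,
                    bias_bandwidth_policy = "same_as_h",
                    variance_estimator = "hc")
  rel <- relative_effect(rd_sharp(ac, config = rcfg), "eligibility")
  set.seed(3001)
  boots <- replicate(2000, {
    idx <- sample.int(nrow(ac), replace = TRUE)
    f <- rd_sharp(ac[idx, ], config = rcfg)
    f$estimate / f$left_limit
  })
  expect_equal(rel$se, sd(boots), tolerance = 0.15)
  bq <- quantile(boots, c(0.025, 0.975))
  width <- bq[2] - bq[1]
  expect_lt(abs(rel$ci[1] - bq[1]), 0.25 * width)
  expect_lt(abs(rel$ci[2] - bq[2]), 0.25 * width)
})

test_that("dementia-type contrasts rank types by their configured effects", {
  base <- synthetic_config(120000, rng_seed = 30,
                           true_itt = c(dementia = -0.02),
                           baseline_outcome_risk = c(dementia = 0.15))
  ppl <- generate_cohort(base)
  tab <- dementia_type_relative_effects(ppl, gender = NULL)
  expect_equal(nrow(tab), 3)
  # equal configured type effects: relative estimates within joint spread
  expect_lt(max(tab$relative) - min(tab$relative), 0.5)

  cfg2 <- synthetic_config(120000, rng_seed = 30,
                           true_itt = c(dementia = -0.02),
                           baseline_outcome_risk = c(dementia = 0.15),
                           dementia_type_effect_ratio = c(alzheimer = 0.5,
                                                          vascular = 0.5,
                                                          mixed = 4, other = 0.5))
  tab2 <- dementia_type_relative_effects(generate_cohort(cfg2), gender = NULL)
  expect_equal(tab2$type[which.min(tab2$relative)], "mixed")

  cfg0 <- synthetic_config(50000, rng_seed = 31, true_itt = c(dementia = 0),
                           baseline_outcome_risk = c(dementia = 0.15))
  tab0 <- dementia_type_relative_effects(generate_cohort(cfg0), gender = NULL)
  expect_true(all(abs(tab0$relative) < 0.4))
})
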
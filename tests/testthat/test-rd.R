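fixed_cfg <- function(h, ...) {
  rd_config(bandwidth_policy = "fixed", bandwidth = h,
            bias_bandwidth_policy = "same_as_h", ...)
}

test_that("triangular kernel weights", {
  expect_equal(kernel_weight(0), 1)
  expect_equal(kernel_weight(0.5), 0.5)
  expect_equal(kernel_weight(c(-0.25, 1.2, -3)), c(0.75, 0, 0))
})

test_that("sharp estimate equals the closed-form weighted least squares oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(20:50, 1)
    x <- sample(-12:12, n, replace = TRUE)
    y <- 0.2 + 0.01 * x + 0.15 * (x >= 0) + rnorm(n, sd = 0.3)
    tb <- tibble::tibble(centered_wob = x, outcome = y)
    h <- sample(6:12, 1)
    fit <- rd_sharp(tb, config = fixed_cfg(h))
    oracle <- wls_oracle(x, y, h)
    expect_lt(abs(fit$estimate - oracle$jump), 1e-10)
    expect_lt(abs(fit$left_limit - oracle$left_intercept), 1e-10)
  }
})

test_that("a data-generating process inside the model class is fit exactly", {
  x <- rep(-30:30, 2)
  y <- 0.1 + 0.002 * x + 0.2 * (x >= 0)
  tb <- tibble::tibble(centered_wob = x, outcome = y)
  for (h in c(10, 20, 30)) {
    fit <- rd_sharp(tb, config = fixed_cfg(h))
    expect_equal(fit$estimate, 0.2, tolerance = 1e-12)
    # no curvature: the bias correction moves nothing
    expect_equal(fit$estimate_bc, 0.2, tolerance = 1e-10)
    expect_lt(fit$se_robust, 1e-10)
  }
  # local quadratic is exact on a quadratic truth
  yq <- 0.1 + 0.002 * x - 1e-4 * x^2 + 0.2 * (x >= 0)
  fitq <- rd_sharp(tibble::tibble(centered_wob = x, outcome = yq),
                   config = fixed_cfg(25, polynomial_order = 2))
  expect_equal(fitq$estimate, 0.2, tolerance = 1e-12)
})

test_that("estimates are invariant to outcome shifts and equivariant to side flips", {
  set.seed(41)
  x <- sample(-40:40, 400, replace = TRUE)
  y <- 0.3 + 0.004 * x + 0.1 * (x >= 0) + rnorm(400, sd = 0.2)
  cfg <- fixed_cfg(25)
  base <- rd_sharp(tibble::tibble(centered_wob = x, outcome = y), config = cfg)
  shift <- rd_sharp(tibble::tibble(centered_wob = x, outcome = y + 5), config = cfg)
  expect_equal(base$estimate, shift$estimate, tolerance = 1e-10)
  expect_equal(base$se_robust, shift$se_robust, tolerance = 1e-10)
  # flipping the running variable swaps sides and negates the jump; the week
  # formerly at 0 lands at -1 to keep a boundary week on the eligible side
  # not exact: the discrete week grid is asymmetric around the boundary, so
  # flipping shifts every mass point's kernel weight by one week
  flip <- rd_sharp(tibble::tibble(centered_wob = -x - 1L, outcome = y), config = cfg)
  expect_equal(flip$estimate, -base$estimate, tolerance = 0.1)
})

test_that("fuzzy estimation satisfies the Wald identity and its guards", {
  ppl <- gen_cohort(20000, seed = 6)
  ac <- analysis_cohort(ppl, "no_cognitive_impairment", "mci")
  cfg <- fixed_cfg(120)
  fz <- rd_fuzzy(ac, config = cfg)
  itt <- rd_sharp(ac, config = cfg)
  expect_lt(abs(fz$estimate * fz$first_stage_jump - itt$estimate), 1e-10)
  expect_lt(abs(fz$estimate_bc * fz$first_stage_jump_bc - itt$estimate_bc), 1e-10)

  # sharp compliance: CACE equals ITT exactly
  cfg_full <- synthetic_config(20000, rng_seed = 61, uptake_right_limit = 1,
                               uptake_right_limit_dementia = 1)
  ac2 <- analysis_cohort(generate_cohort(cfg_full), "no_cognitive_impairment", "mci")
  fz2 <- rd_fuzzy(ac2, config = cfg)
  expect_equal(fz2$first_stage_jump, 1, tolerance = 1e-10)
  expect_equal(fz2$estimate, rd_sharp(ac2, config = cfg)$estimate, tolerance = 1e-10)

  # no uptake jump at all: explicit weak-instrument error
  cfg_null <- synthetic_config(5000, rng_seed = 62, uptake_right_limit = 0,
                               uptake_right_limit_dementia = 0,
                               true_itt = c(mci = 0))
  ac3 <- analysis_cohort(generate_cohort(cfg_null), "no_cognitive_impairment", "mci")
  expect_error(rd_fuzzy(ac3, config = cfg), "weak first stage")
})

test_that("insufficient support and collinear covariates raise informative errors", {
  tb <- tibble::tibble(centered_wob = c(-1, -1, -1, 0, 1, 2, 3),
                       outcome = rnorm(7))
  expect_error(rd_sharp(tb, config = fixed_cfg(3)), "left side")
  ppl <- gen_cohort(5000, seed = 7)
  ac <- analysis_cohort(ppl, "all", "mci")
  ac$dup <- as.numeric(ac$charlson_diabetes)
  ac$dup2 <- ac$dup
  cfg <- fixed_cfg(150)
  cfg$covariates <- c("dup", "dup2")
  expect_error(rd_sharp(ac, config = cfg), "collinear covariates.*dup")
})

test_that("additive covariate adjustment removes covariate-driven noise", {
  set.seed(55)
  x <- sample(-60:60, 4000, replace = TRUE)
  z <- rnorm(4000)
  y_clean <- 0.2 + 0.002 * x + 0.05 * (x >= 0) + rnorm(4000, sd = 0.05)
  y <- y_clean + 0.8 * z
  cfg <- fixed_cfg(40)
  cfg_adj <- fixed_cfg(40)
  cfg_adj$covariates <- "z"
  tb <- tibble::tibble(centered_wob = x, outcome = y, z = z)
  fit_adj <- rd_sharp(tb, config = cfg_adj)
  fit_clean <- rd_sharp(tibble::tibble(centered_wob = x, outcome = y_clean),
                        config = cfg)
  expect_equal(fit_adj$estimate, fit_clean$estimate, tolerance = 0.01)
  expect_lt(fit_adj$se_robust,
            rd_sharp(tb, config = cfg)$se_robust)
})

test_that("plug-in bandwidth is scale-equivariant and shrinks at the n^(-1/5) rate", {
  set.seed(77)
  n <- 8000
  # curvature on one side only, so the boundary bias contrast is nonzero
  dgp <- function(xx) 0.3 + 0.001 * xx + 3e-5 * xx^2 * (xx >= 0) +
    rnorm(length(xx), sd = 0.15)
  x <- round(runif(n, -200, 200))
  y <- dgp(x)
  tb <- tibble::tibble(centered_wob = x, outcome = y)
  bw <- select_bandwidth_mse(tb)
  tb2 <- tibble::tibble(centered_wob = 2 * x, outcome = y)
  bw2 <- select_bandwidth_mse(tb2)
  expect_equal(bw2$h / bw$h, 2, tolerance = 1e-6)
  expect_equal(bw2$b / bw$b, 2, tolerance = 1e-6)

  # rate: 10x the sample under the same DGP shrinks h by about 10^(-1/5)
  hs <- sapply(c(3000, 30000), function(m) {
    mean(sapply(1:8, function(s) {
      set.seed(1000 + s + m)
      xx <- round(runif(m, -200, 200))
      select_bandwidth_mse(tibble::tibble(centered_wob = xx, outcome = dgp(xx)))$h
    }))
  })
  expect_equal(hs[2] / hs[1], 10^(-1 / 5), tolerance = 0.12)

  expect_error(select_bandwidth_mse(tb[tb$centered_wob > -3, ]),
               "observations per side")
})

test_that("plug-in bandwidth matches an independent re-derivation within 2%", {
  set.seed(88)
  n <- 12000
  x <- round(runif(n, -250, 250))
  y <- rbinom(n, 1, plogis(-1.5 + 0.003 * x - 4e-5 * x^2 * (x >= 0)))
  tb <- tibble::tibble(centered_wob = x, outcome = y)
  got <- select_bandwidth_mse(tb)$h

  # independent implementation of the same plug-in: numeric kernel integrals,
  # pilot fits via lm with poly terms written out
  S <- outer(0:1, 0:1, Vectorize(function(a, b)
    integrate(function(u) u^(a + b) * (1 - u), 0, 1)$value))
  Tm <- outer(0:1, 0:1, Vectorize(function(a, b)
    integrate(function(u) u^(a + b) * (1 - u)^2, 0, 1)$value))
  cc <- sapply(0:1, function(j) integrate(function(u) u^(j + 2) * (1 - u), 0, 1)$value)
  Cb <- solve(S, cc)[1]
  Cv <- (solve(S) %*% Tm %*% solve(S))[1, 1]
  rot <- 1.84 * sd(x) * n^(-0.2)
  f0 <- mean(abs(x) <= rot) / (2 * rot)
  s2 <- var(y[x >= 0 & x <= rot]) + var(y[x < 0 & x >= -rot])
  cub <- function(s, yy) {
    fit <- lm(yy ~ s + I(s^2) + I(s^3))
    c(coef(fit)["I(s^2)"], sqrt(diag(vcov(fit)))["I(s^2)"])
  }
  r <- cub(x[x >= 0], y[x >= 0]); l <- cub(-x[x < 0], y[x < 0])
  B2 <- (r[1] - l[1])^2 + r[2]^2 + l[2]^2
  expected <- (Cv * s2 / f0 / (4 * Cb^2 * B2))^(1 / 5) * n^(-1 / 5)
  expect_equal(got, unname(expected), tolerance = 0.02)
})

test_that("robust bias correction restores coverage under curvature", {
  # curvature strong enough that the conventional local-linear interval at a
  # too-wide bandwidth undercovers, while the robust interval does not
  truth <- 0.05
  sim <- function(s) {
    set.seed(s)
    x <- round(runif(3000, -100, 100))
    y <- 0.3 + truth * (x >= 0) + 0.001 * x + 3e-5 * x^2 * (x >= 0) +
      rnorm(3000, sd = 0.1)
    fit <- rd_sharp(tibble::tibble(centered_wob = x, outcome = y),
                    config = fixed_cfg(80))
    c(conv = fit$ci_conventional[1] <= truth & truth <= fit$ci_conventional[2],
      rob = fit$ci_robust[1] <= truth & truth <= fit$ci_robust[2])
  }
  cover <- rowMeans(sapply(1:150, sim))
  expect_lt(cover["conv"], 0.80)
  expect_gt(cover["rob"], 0.90)
})
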
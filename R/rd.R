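# Local-polynomial regression-discontinuity engine.
#
# Both the conventional and the bias-corrected boundary estimates are linear
# functionals of the outcome, so every estimator here is represented by an
# explicit weight vector over observations. Robust (bias-corrected) variances
# are sandwich variances of those weight vectors, by default clustered on the
# mass points of the discrete weekly running variable.

#' Triangular kernel weight
#'
#' @param u bandwidth-scaled distance from the threshold.
#' @return `max(0, 1 - |u|)`.
#' @export
kernel_weight <- function(u) pmax(0, 1 - abs(u))

#' Settings for regression-discontinuity estimation
#'
#' @param polynomial_order local polynomial order (1 = local linear, 2 =
#'   local quadratic; higher orders are deliberately not offered).
#' @param kernel kernel for distance weighting (triangular).
#' @param bandwidth_policy `"mse_optimal"` (plug-in, the default), `"fixed"`
#'   (use `bandwidth`), or `"multiplier"` (scale the MSE-optimal bandwidth by
#'   `bandwidth_multiplier`, for robustness grids).
#' @param bandwidth fixed main bandwidth in weeks (policy `"fixed"`).
#' @param bias_bandwidth optional fixed bias bandwidth in weeks (policy
#'   `"fixed"`); floored at the main bandwidth.
#' @param bandwidth_multiplier factor applied to the MSE-optimal bandwidth.
#' @param bias_order polynomial order of the bias-correction fit (default
#'   `polynomial_order + 1`).
#' @param bias_bandwidth_policy `"mse_optimal_derivative"` selects a separate
#'   plug-in bandwidth for the curvature estimand; `"same_as_h"` reuses the
#'   main bandwidth. The bias bandwidth is never allowed below the main one.
#' @param variance_estimator `"cluster_by_week"` (default; conservative for
#'   the discrete running variable) or `"hc"` (heteroskedasticity-robust).
#' @param covariates columns entering the local regression additively with
#'   coefficients common to both sides.
#' @param fixed_effects factor columns expanded to indicator covariates
#'   (e.g. rollout cohort under the staggered index-date policy).
#' @param first_stage_guard minimum admissible first-stage jump for fuzzy
#'   estimation.
#' @param alpha nominal level for confidence intervals.
#' @param min_obs_per_side floor on observations per side for bandwidth
#'   selection.
#' @return an `rd_config` object.
#' @export
rd_config <- function(polynomial_order = 1,
                      kernel = "triangular",
                      bandwidth_policy = c("mse_optimal", "fixed", "multiplier"),
                      bandwidth = NULL,
                      bias_bandwidth = NULL,
                      bandwidth_multiplier = 1,
                      bias_order = polynomial_order + 1,
                      bias_bandwidth_policy = c("mse_optimal_derivative", "same_as_h"),
                      variance_estimator = c("cluster_by_week", "hc"),
                      covariates = character(),
                      fixed_effects = character(),
                      first_stage_guard = 0.01,
                      alpha = 0.05,
                      min_obs_per_side = 50) {
  if (!polynomial_order %in% 1:2) stop_field("polynomial_order", "must be 1 or 2")
  kernel <- match.arg(kernel, "triangular")
  bandwidth_policy <- match.arg(bandwidth_policy)
  if (bandwidth_policy == "fixed") {
    if (is.null(bandwidth) || !is.finite(bandwidth) || bandwidth <= 0) {
      stop_field("bandwidth", "fixed policy requires a positive bandwidth")
    }
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) stop_field("alpha", "must lie in (0, 1)")
  structure(list(
    polynomial_order = as.integer(polynomial_order),
    kernel = kernel,
    bandwidth_policy = bandwidth_policy,
    bandwidth = bandwidth,
    bias_bandwidth = bias_bandwidth,
    bandwidth_multiplier = bandwidth_multiplier,
    bias_order = as.integer(bias_order),
    bias_bandwidth_policy = match.arg(bias_bandwidth_policy),
    variance_estimator = match.arg(variance_estimator),
    covariates = covariates,
    fixed_effects = fixed_effects,
    first_stage_guard = first_stage_guard,
    alpha = alpha,
    min_obs_per_side = min_obs_per_side
  ), class = "rd_config")
}

# ---- kernel moment constants ----------------------------------------------
# Boundary local-polynomial asymptotics for the triangular kernel use the
# moment matrices S_jk = int_0^1 u^(j+k) K(u) du, T_jk = int u^(j+k) K(u)^2 du
# and c_j = int u^(j+p+1) K(u) du, which are rational for K(u) = 1 - u:
#   int u^m (1-u)   du = 1 / ((m+1)(m+2))
#   int u^m (1-u)^2 du = 2 / ((m+1)(m+2)(m+3))
tri_m1 <- function(m) 1 / ((m + 1) * (m + 2))
tri_m2 <- function(m) 2 / ((m + 1) * (m + 2) * (m + 3))

kernel_constants <- function(p, nu) {
  j <- 0:p
  S <- outer(j, j, function(a, b) tri_m1(a + b))
  Tm <- outer(j, j, function(a, b) tri_m2(a + b))
  cc <- tri_m1(j + p + 1)
  Sinv <- solve(S)
  list(
    # bias of the m^(nu) estimator: Cb * h^(p+1-nu) * m^(p+1)(0) / (p+1)!
    Cb = (Sinv %*% cc)[nu + 1] * factorial(nu),
    # variance: Cv * sigma^2 / (f0 * n * h^(1+2*nu))
    Cv = (Sinv %*% Tm %*% Sinv)[nu + 1, nu + 1] * factorial(nu)^2
  )
}

# ---- boundary fit primitives ----------------------------------------------

vanderm <- function(s, p) outer(s, 0:p, `^`)

# weight rows of a one-sided order-p fit at bandwidth h: A = (X'KX)^-1 X'K,
# so coef = A %*% y. s are nonnegative distances from the threshold.
side_projection <- function(s, h, p, side) {
  k <- kernel_weight(s / h)
  if (length(unique(s[k > 0])) <= p) {
    stop(sprintf("insufficient support on the %s side within bandwidth %.2f", side, h),
         call. = FALSE)
  }
  X <- vanderm(s, p)
  M <- crossprod(X, k * X)
  A <- solve(M, t(X * k))
  list(A = A, X = X, k = k)
}

# one side of the bias-corrected boundary level estimator, in local
# coordinates s = distance >= 0. Returns full-support weight vectors and the
# residual vector used by the sandwich variance.
side_weights <- function(s, y, h, b, p, q, side) {
  ph <- side_projection(s, h, p, side)
  l_p <- ph$A[1, ]
  coef_p <- drop(ph$A %*% y)
  fit_p <- drop(ph$X %*% coef_p)

  qb <- side_projection(s, b, q, side)
  d <- qb$A[q + 1, ]                      # coefficient on s^q at bandwidth b
  coef_q <- drop(qb$A %*% y)
  fit_q <- drop(qb$X %*% coef_q)

  load <- sum(l_p * s^q)                  # loading of the order-p fit on s^q
  l_bc <- l_p - load * d

  in_b <- qb$k > 0
  in_h <- ph$k > 0
  r_bc <- ifelse(in_b, y - fit_q, ifelse(in_h, y - fit_p, 0))
  r_conv <- ifelse(in_h, y - fit_p, 0)
  list(l_conv = l_p, l_bc = l_bc, r_bc = r_bc, r_conv = r_conv,
       level_conv = sum(l_p * y), level_bc = sum(l_bc * y),
       n_eff = sum(s <= h))
}

cluster_var <- function(w, r, cluster, type) {
  psi <- w * r
  if (type == "cluster_by_week") {
    sums <- rowsum(psi, cluster)
    g <- sum(abs(rowsum(abs(w), cluster)) > 0)
    sum(sums^2) * if (g > 1) g / (g - 1) else 1
  } else {
    sum(psi^2)
  }
}

# additive covariate adjustment with coefficients common to both sides:
# gamma from the kernel-weighted order-p regression within h, then the
# adjusted outcome y - Z gamma feeds the univariate machinery.
partial_out_covariates <- function(x, y, h, p, Z) {
  k <- kernel_weight(x / h)
  use <- k > 0
  # columns constant on the kernel support (e.g. fixed-effect levels outside
  # the bandwidth) carry no information for the local fit and are dropped
  informative <- apply(Z[use, , drop = FALSE], 2, function(col) stats::var(col) > 0)
  Z <- Z[, informative, drop = FALSE]
  if (ncol(Z) == 0L) return(y)
  D <- as.numeric(x >= 0)
  X <- cbind(1, D)
  for (j in seq_len(p)) X <- cbind(X, x^j, D * x^j)
  X <- cbind(X, Z)
  qrX <- qr(sqrt(k[use]) * X[use, , drop = FALSE])
  if (qrX$rank < ncol(X)) {
    drop_idx <- qrX$pivot[(qrX$rank + 1):ncol(X)]
    znames <- colnames(Z) %||% paste0("z", seq_len(ncol(Z)))
    offending <- drop_idx[drop_idx > 2 * (p + 1)] - 2 * (p + 1)
    stop(paste("collinear covariates:",
               paste(znames[offending], collapse = ", ")), call. = FALSE)
  }
  beta <- qr.coef(qrX, sqrt(k[use]) * y[use])
  gamma <- beta[(2 * (p + 1) + 1):length(beta)]
  y - drop(Z %*% gamma)
}

build_covariate_matrix <- function(data, config) {
  cols <- config$covariates
  Z <- NULL
  if (length(cols)) {
    missing <- setdiff(cols, names(data))
    if (length(missing)) stop(paste("missing covariate column(s):",
                                    paste(missing, collapse = ", ")), call. = FALSE)
    Z <- as.matrix(data.frame(lapply(data[cols], as.numeric)))
  }
  if (length(config$fixed_effects)) {
    for (fe in config$fixed_effects) {
      f <- factor(data[[fe]])
      if (nlevels(f) > 1L) {
        mm <- stats::model.matrix(~ f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(fe, "_", levels(f)[-1])
        Z <- if (is.null(Z)) mm else cbind(Z, mm)
      }
    }
  }
  Z
}

# core engine shared by sharp and fuzzy estimation; x in weeks, y numeric.
rd_engine <- function(x, y, h, b, p, q, variance, alpha) {
  left <- x < 0
  L <- side_weights(-x[left], y[left], h, b, p, q, "left")
  R <- side_weights(x[!left], y[!left], h, b, p, q, "right")
  full <- function(lv, rv) {
    out <- numeric(length(x))
    out[left] <- -lv
    out[!left] <- rv
    out
  }
  resid_full <- function(lr, rr) {
    out <- numeric(length(x))
    out[left] <- lr
    out[!left] <- rr
    out
  }
  w_conv <- full(L$l_conv, R$l_conv)
  w_bc <- full(L$l_bc, R$l_bc)
  r_bc <- resid_full(L$r_bc, R$r_bc)
  r_conv <- resid_full(L$r_conv, R$r_conv)
  tau_conv <- R$level_conv - L$level_conv
  tau_bc <- R$level_bc - L$level_bc
  se_conv <- sqrt(cluster_var(w_conv, r_conv, x, variance))
  se_rob <- sqrt(cluster_var(w_bc, r_bc, x, variance))
  z <- stats::qnorm(1 - alpha / 2)
  list(tau_conv = tau_conv, tau_bc = tau_bc,
       se_conv = se_conv, se_rob = se_rob,
       ci_robust = c(tau_bc - z * se_rob, tau_bc + z * se_rob),
       ci_conventional = c(tau_conv - z * se_conv, tau_conv + z * se_conv),
       p_robust = 2 * stats::pnorm(-abs(tau_bc / se_rob)),
       left_limit = L$level_conv, right_limit = R$level_conv,
       left_limit_bc = L$level_bc, right_limit_bc = R$level_bc,
       n_eff_left = L$n_eff, n_eff_right = R$n_eff,
       w_conv = w_conv, w_bc = w_bc, r_bc = r_bc, r_conv = r_conv,
       w_left_conv = full(L$l_conv, numeric(sum(!left))) * -1, # +weights for left level
       w_right_conv = full(numeric(sum(left)), R$l_conv))
}

#' Plug-in MSE-optimal bandwidths
#'
#' Selects the main bandwidth `h` for the order-`p` boundary jump estimator
#' and the bias bandwidth `b` for the order-`q` curvature estimand, using a
#' plug-in mean-squared-error criterion: pilot curvature from one-sided
#' global polynomial fits (leading-coefficient differences, regularised by
#' their estimation variance), boundary outcome variance and running-variable
#' density from a pilot window, and closed-form triangular-kernel constants.
#' `h` scales as `n^(-1/(2p+3))`; degenerate pilots fall back to a
#' rule-of-thumb bandwidth with a warning.
#'
#' @param data analysis cohort (or any table with the two columns below).
#' @param outcome outcome column name.
#' @param config an [rd_config()].
#' @param running running-variable column name.
#' @return list with elements `h` and `b` (weeks).
#' @export
select_bandwidth_mse <- function(data, outcome = "outcome", config = rd_config(),
                                 running = "centered_wob") {
  x <- as.numeric(data[[running]])
  y <- as.numeric(data[[outcome]])
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (sum(x >= 0) < config$min_obs_per_side || sum(x < 0) < config$min_obs_per_side) {
    stop(sprintf("need at least %d observations per side for bandwidth selection",
                 config$min_obs_per_side), call. = FALSE)
  }
  p <- config$polynomial_order
  q <- config$bias_order
  rot <- 1.84 * stats::sd(x) * n^(-1 / 5)
  fallback <- function(msg) {
    warning(paste("bandwidth plug-in degenerate:", msg,
                  "- falling back to rule of thumb"), call. = FALSE)
    list(h = rot, b = 1.5 * rot)
  }
  f0 <- mean(abs(x) <= rot) / (2 * rot)
  sig2 <- function(side) {
    yy <- y[if (side == "right") x >= 0 & x <= rot else x < 0 & x >= -rot]
    if (length(yy) < 5) return(NA_real_)
    stats::var(yy)
  }
  s2 <- sig2("left") + sig2("right")
  if (!is.finite(s2) || s2 <= 0 || !is.finite(f0) || f0 <= 0) {
    return(fallback("boundary variance or density not estimable"))
  }
  # leading-coefficient difference of one-sided polynomial fits in the local
  # distance coordinate: estimates the (order+1) derivative contrast driving
  # the bias, regularised by its own sampling variance so near-zero curvature
  # yields a wide but finite bandwidth
  lead_coef <- function(order) {
    # Taylor coefficient of s^order at the boundary, from a one-sided global
    # fit of order (order + 1) so the target coefficient is not the highest
    est <- function(side) {
      s <- if (side == "right") x[x >= 0] else -x[x < 0]
      yy <- if (side == "right") y[x >= 0] else y[x < 0]
      fit <- stats::lm(yy ~ vanderm(s, order + 1) - 1)
      cf <- unname(stats::coef(fit)[order + 1])
      se <- unname(sqrt(diag(stats::vcov(fit)))[order + 1])
      c(cf, se)
    }
    r <- est("right"); l <- est("left")
    c(diff = unname(r[1] - l[1]), var = unname(r[2]^2 + l[2]^2))
  }
  pilot_h <- lead_coef(p + 1)
  if (!all(is.finite(pilot_h))) return(fallback("curvature pilot failed"))
  kc <- kernel_constants(p, 0)
  B2 <- pilot_h[["diff"]]^2 + pilot_h[["var"]]
  h <- (kc$Cv * s2 / f0 / (2 * (p + 1) * kc$Cb^2 * B2))^(1 / (2 * p + 3)) *
    n^(-1 / (2 * p + 3))
  pilot_b <- lead_coef(q + 1)
  kcq <- kernel_constants(q, q)
  B2b <- pilot_b[["diff"]]^2 + pilot_b[["var"]]
  bb <- ((2 * q + 1) * kcq$Cv * s2 / f0 / (2 * kcq$Cb^2 * B2b))^(1 / (2 * q + 3)) *
    n^(-1 / (2 * q + 3))
  if (!is.finite(h) || h <= 0 || !is.finite(bb) || bb <= 0) {
    return(fallback("non-finite plug-in solution"))
  }
  list(h = h, b = max(bb, h))
}

resolve_bandwidths <- function(data, outcome, config, running = "centered_wob") {
  if (config$bandwidth_policy == "fixed") {
    h <- config$bandwidth
    b <- if (!is.null(config$bias_bandwidth)) {
      max(config$bias_bandwidth, h)
    } else if (config$bias_bandwidth_policy == "same_as_h") {
      h
    } else {
      sel <- tryCatch(select_bandwidth_mse(data, outcome, config, running),
                      warning = function(w) NULL, error = function(e) NULL)
      max(if (is.null(sel)) 1.5 * h else sel$b, h)
    }
    return(list(h = h, b = b))
  }
  sel <- select_bandwidth_mse(data, outcome, config, running)
  h <- sel$h
  if (config$bandwidth_policy == "multiplier") h <- h * config$bandwidth_multiplier
  b <- if (config$bias_bandwidth_policy == "same_as_h") h else max(sel$b, h)
  list(h = h, b = b)
}

rd_prepare <- function(data, outcome, config, running) {
  x <- as.numeric(data[[running]])
  y <- as.numeric(data[[outcome]])
  ok <- !is.na(x) & !is.na(y)
  Z <- build_covariate_matrix(data, config)
  list(x = x[ok], y = y[ok], Z = if (is.null(Z)) NULL else Z[ok, , drop = FALSE])
}

rd_result <- function(kind, fit, h, b, config, extra = list()) {
  structure(c(list(
    kind = kind,
    estimate = fit$tau_conv,
    estimate_bc = fit$tau_bc,
    se_conventional = fit$se_conv,
    se_robust = fit$se_rob,
    ci_robust = fit$ci_robust,
    ci_conventional = fit$ci_conventional,
    p_robust = fit$p_robust,
    bandwidth_h = h,
    bandwidth_b = b,
    n_eff_left = fit$n_eff_left,
    n_eff_right = fit$n_eff_right,
    left_limit = fit$left_limit,
    alpha = config$alpha,
    config = config
  ), extra), class = "rd_result")
}

#' Sharp regression-discontinuity estimate (intent-to-treat)
#'
#' Estimates the jump in the outcome at the threshold by kernel-weighted
#' local polynomial regression with separate slopes on each side, restricted
#' to the bandwidth, with robust bias-corrected inference: the order-`q` fit
#' at the bias bandwidth estimates the leading smoothing bias, which is
#' subtracted from the point estimate while its sampling variability is
#' folded into the reported standard error. The robust interval is centred on
#' the bias-corrected estimate and therefore need not contain the
#' conventional one.
#'
#' @param data analysis cohort (see [analysis_cohort()]).
#' @param outcome outcome column.
#' @param config an [rd_config()].
#' @param running running-variable column.
#' @return an `rd_result`.
#' @export
rd_sharp <- function(data, outcome = "outcome", config = rd_config(),
                     running = "centered_wob") {
  prep <- rd_prepare(data, outcome, config, running)
  bw <- resolve_bandwidths(data, outcome, config, running)
  y <- prep$y
  if (!is.null(prep$Z)) {
    y <- partial_out_covariates(prep$x, y, bw$h, config$polynomial_order, prep$Z)
  }
  fit <- rd_engine(prep$x, y, bw$h, bw$b, config$polynomial_order,
                   config$bias_order, config$variance_estimator, config$alpha)
  rd_result("sharp", fit, bw$h, bw$b, config,
            extra = list(internals = list(x = prep$x, y = y, fit = fit)))
}

#' Fuzzy regression-discontinuity estimate (complier average causal effect)
#'
#' Two-stage least squares with eligibility as the instrument for receipt,
#' sharing the bandwidth and kernel weights of the intent-to-treat fit: the
#' point estimate is the ratio of the outcome jump to the first-stage uptake
#' jump, and robust bias-corrected inference uses the delta method on the
#' bias-corrected numerator and denominator with their full covariance
#' (clustered by week).
#'
#' @param data analysis cohort.
#' @param outcome outcome column.
#' @param receipt treatment-receipt column.
#' @param config an [rd_config()].
#' @param running running-variable column.
#' @return an `rd_result` with `first_stage_jump`.
#' @export
rd_fuzzy <- function(data, outcome = "outcome", receipt = "vaccinated",
                     config = rd_config(), running = "centered_wob") {
  prep <- rd_prepare(data, outcome, config, running)
  v <- as.numeric(data[[receipt]])[!is.na(data[[running]]) & !is.na(data[[outcome]])]
  bw <- resolve_bandwidths(data, outcome, config, running)
  y <- prep$y
  if (!is.null(prep$Z)) {
    y <- partial_out_covariates(prep$x, y, bw$h, config$polynomial_order, prep$Z)
  }
  p <- config$polynomial_order
  q <- config$bias_order
  fy <- rd_engine(prep$x, y, bw$h, bw$b, p, q, config$variance_estimator, config$alpha)
  fv <- rd_engine(prep$x, v, bw$h, bw$b, p, q, config$variance_estimator, config$alpha)
  if (abs(fv$tau_conv) < config$first_stage_guard) {
    stop(sprintf("weak first stage: uptake jump %.4f below guard %.3f",
                 fv$tau_conv, config$first_stage_guard), call. = FALSE)
  }
  tau_conv <- fy$tau_conv / fv$tau_conv
  tau_bc <- fy$tau_bc / fv$tau_bc
  # delta-method influence of the ratio, clustered like the components
  infl <- function(tau, wY, rY, wV, rV, denom) (wY * rY - tau * (wV * rV)) / denom
  se_rob <- sqrt(cluster_sum2(infl(tau_bc, fy$w_bc, fy$r_bc, fv$w_bc, fv$r_bc, fv$tau_bc),
                              prep$x, config$variance_estimator))
  se_conv <- sqrt(cluster_sum2(infl(tau_conv, fy$w_conv, fy$r_conv, fv$w_conv, fv$r_conv,
                                    fv$tau_conv),
                               prep$x, config$variance_estimator))
  z <- stats::qnorm(1 - config$alpha / 2)
  fit <- list(tau_conv = tau_conv, tau_bc = tau_bc, se_conv = se_conv, se_rob = se_rob,
              ci_robust = c(tau_bc - z * se_rob, tau_bc + z * se_rob),
              ci_conventional = c(tau_conv - z * se_conv, tau_conv + z * se_conv),
              p_robust = 2 * stats::pnorm(-abs(tau_bc / se_rob)),
              left_limit = fy$left_limit, n_eff_left = fy$n_eff_left,
              n_eff_right = fy$n_eff_right)
  rd_result("fuzzy", fit, bw$h, bw$b, config,
            extra = list(first_stage_jump = fv$tau_conv,
                         first_stage_jump_bc = fv$tau_bc,
                         itt = fy$tau_conv,
                         internals = list(x = prep$x, y = y, v = v,
                                          fit_y = fy, fit_v = fv)))
}

cluster_sum2 <- function(psi, cluster, type) {
  if (type == "cluster_by_week") {
    sums <- rowsum(psi, cluster)
    g <- nrow(sums)
    sum(sums^2) * if (g > 1) g / (g - 1) else 1
  } else {
    sum(psi^2)
  }
}

#' @export
print.rd_result <- function(x, ...) {
  cat(sprintf("%s RD estimate (order %d, h = %.1f, b = %.1f weeks)\n",
              x$kind, x$config$polynomial_order, x$bandwidth_h, x$bandwidth_b))
  cat(sprintf("  estimate (conventional): %+.4f\n", x$estimate))
  cat(sprintf("  bias-corrected:          %+.4f  robust SE %.4f\n",
              x$estimate_bc, x$se_robust))
  cat(sprintf("  robust %d%% CI: [%+.4f, %+.4f]  p = %.4f\n",
              round(100 * (1 - x$alpha)), x$ci_robust[1], x$ci_robust[2], x$p_robust))
  if (!is.null(x$first_stage_jump)) {
    cat(sprintf("  first-stage jump: %.4f\n", x$first_stage_jump))
  }
  cat(sprintf("  effective N: %d (left) / %d (right)\n", x$n_eff_left, x$n_eff_right))
  invisible(x)
}
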
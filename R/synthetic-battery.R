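#' Effect configuration for the synthetic cognitive battery
#'
#' Standardized generating effects for the four latent cognitive factors
#' (processing speed, memory, spatial/reasoning, vocabulary). Defaults are
#' calibrated to the published standardized coefficients: age-acceleration
#' effects of -0.31, -0.33, -0.26, -0.24, age effects of -0.39, -0.45,
#' -0.33, -0.20 and per-session (practice) effects of 0.06, 0.01, 0.02,
#' -0.18. Factor residuals are correlated compound-symmetrically at 0.45 by
#' default, mimicking the positive inter-domain correlations of the
#' cognitive positive manifold.
#'
#' The residual SD of each latent factor is solved internally so that every
#' factor has unit population variance, which makes the configured betas
#' directly interpretable as standardized regression coefficients.
#'
#' @param beta_accel,beta_age,beta_session length-4 standardized effects per
#'   factor (age acceleration, age, session number).
#' @param factor_corr 4x4 correlation matrix of the factor residuals.
#' @param item_loading loading of each item on its factor, in (0, 1].
#' @param item_noise_sd SD of item-specific noise; the default
#'   `sqrt(1 - item_loading^2)` gives unit-variance items with reliability
#'   `item_loading^2` (about 0.5, typical of single cognitive scales).
#' @param subject_re_sd length-2 SDs of the per-subject random intercept and
#'   random session slope.
#' @return A list of class `effect_config`.
#' @export
effect_config <- function(beta_accel = c(-0.31, -0.33, -0.26, -0.24),
                          beta_age = c(-0.39, -0.45, -0.33, -0.20),
                          beta_session = c(0.06, 0.01, 0.02, -0.18),
                          factor_corr = NULL,
                          item_loading = 0.7,
                          item_noise_sd = sqrt(1 - item_loading^2),
                          subject_re_sd = c(0.5, 0.1)) {
  if (is.null(factor_corr)) {
    factor_corr <- matrix(0.45, 4, 4)
    diag(factor_corr) <- 1
  }
  stopifnot(length(beta_accel) == 4L, length(beta_age) == 4L,
            length(beta_session) == 4L, length(subject_re_sd) == 2L)
  if (!all(is.finite(c(beta_accel, beta_age, beta_session)))) {
    stop("invalid config: effect sizes must be finite", call. = FALSE)
  }
  if (item_loading <= 0 || item_loading > 1) {
    stop("invalid config: item_loading must lie in (0, 1]", call. = FALSE)
  }
  structure(list(
    beta_accel = as.numeric(beta_accel),
    beta_age = as.numeric(beta_age),
    beta_session = as.numeric(beta_session),
    factor_corr = .check_pd_corr(factor_corr, "factor_corr"),
    item_loading = as.numeric(item_loading),
    item_noise_sd = as.numeric(item_noise_sd),
    subject_re_sd = as.numeric(subject_re_sd)
  ), class = "effect_config")
}

#' Generate the session-level cognitive battery for a synthetic cohort
#'
#' For subject s in session t, latent factor f is
#' `beta_age[f] * z(age) + beta_accel[f] * z(accel) + beta_session[f] * t +
#' u0[s,f] + u1[s,f] * t + e[s,t,f]`, with subject random intercepts/slopes
#' and factor residuals drawn from `factor_corr` scaled so each factor has
#' unit population variance. Each of the 15 items is
#' `item_loading * factor + item_noise_sd * noise`, standardized across the
#' pooled sample (the analysis operates on standardized scores; raw test
#' scales are not reproduced, and pooled standardization preserves the
#' calibrated per-session practice effects). The spatial/reasoning factor
#' carries its six items; the other factors carry three each.
#'
#' @param cohort a subject-level table from [generate_cohort()].
#' @param effects an [effect_config()].
#' @param seed integer seed.
#' @param n_sessions number of sessions (default 3).
#' @return A long-format `data.frame` (one row per subject x session) with
#'   the cohort covariates, `session`, and the 15 item columns. The latent
#'   factor values are attached as attribute `"latent_factors"` (matrix with
#'   columns per factor).
#' @export
generate_cognitive_battery <- function(cohort, effects = effect_config(), seed,
                                       n_sessions = 3L) {
  stopifnot(inherits(effects, "effect_config"), is.data.frame(cohort))
  n_sessions <- .check_count(n_sessions, "n_sessions")
  set.seed(seed)

  n <- nrow(cohort)
  sess_vals <- seq_len(n_sessions)
  v_sess <- mean((sess_vals - mean(sess_vals))^2)   # population variance of t
  m_sess2 <- mean(sess_vals^2)                      # E[t^2]

  tau0 <- effects$subject_re_sd[1]
  tau1 <- effects$subject_re_sd[2]
  resid_var <- 1 - (effects$beta_accel^2 + effects$beta_age^2 +
                    effects$beta_session^2 * v_sess +
                    tau0^2 + tau1^2 * m_sess2)
  if (any(resid_var <= 0)) {
    stop("invalid config: configured effects and random-effect SDs imply ",
         "non-positive factor residual variance", call. = FALSE)
  }
  resid_sd <- sqrt(resid_var)
  sigma_e <- diag(resid_sd) %*% effects$factor_corr %*% diag(resid_sd)

  z_age <- .zscore(cohort$age)
  z_accel <- .zscore(cohort$accel)

  u0 <- matrix(rnorm(n * 4L, 0, tau0), n, 4L)
  u1 <- matrix(rnorm(n * 4L, 0, tau1), n, 4L)

  long <- data.frame(
    row = rep(seq_len(n), each = n_sessions),
    session = rep(sess_vals, times = n)
  )
  nr <- nrow(long)

  e <- MASS::mvrnorm(nr, mu = rep(0, 4L), Sigma = sigma_e)
  factors <- matrix(0, nr, 4L, dimnames = list(NULL, names(battery_items())))
  for (f in 1:4) {
    factors[, f] <- effects$beta_age[f] * z_age[long$row] +
      effects$beta_accel[f] * z_accel[long$row] +
      effects$beta_session[f] * long$session +
      u0[long$row, f] + u1[long$row, f] * long$session + e[, f]
  }

  items <- battery_items()
  item_names <- unlist(items, use.names = FALSE)
  item_mat <- matrix(0, nr, length(item_names),
                     dimnames = list(NULL, item_names))
  for (f in seq_along(items)) {
    for (it in items[[f]]) {
      item_mat[, it] <- effects$item_loading * factors[, f] +
        if (effects$item_noise_sd > 0) rnorm(nr, 0, effects$item_noise_sd) else 0
    }
  }
  # standardize items across the pooled sample; pooled (not within-session)
  # standardization keeps the calibrated per-session practice effects in the
  # standardized scores
  item_mat <- scale(item_mat)

  out <- cbind(cohort[long$row, , drop = FALSE],
               session = long$session,
               as.data.frame(item_mat, check.names = FALSE))
  rownames(out) <- NULL
  attr(out, "latent_factors") <- factors
  out
}
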
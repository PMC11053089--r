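make_design_toy <- function() {
  fx <- default_battery()
  bat <- fx$battery
  X <- session_mean_items(bat)
  e <- ega(X, seed = 1)
  sc <- network_scores(as.matrix(bat[, item_names()]), e$graph$W,
                       e$communities)
  list(bat = bat, scores = sc)
}

test_that("build_design assembles the standardized coefficient table layout", {
  toy <- make_design_toy()
  des <- build_design(toy$bat, toy$scores)
  expect_equal(des$terms,
               c("(Intercept)", "AgeAccelGrim", "Age", "TimeDiff", "Session",
                 "SexFemale", cell_count_names()))
  # standardized columns: mean 0, SD 1
  for (cn in c("AgeAccelGrim", "Age", "TimeDiff")) {
    expect_lt(abs(mean(des$X[, cn])), 1e-12)
    expect_lt(abs(sd(des$X[, cn]) - 1), 1e-12)
  }
  expect_true(all(des$X[, "Session"] %in% 1:3))
  expect_true(all(des$X[, "SexFemale"] %in% 0:1))
  expect_lt(max(abs(colMeans(des$Y))), 1e-12)

  # small-cohort hand layout
  ids <- sprintf("S%03d", 1:20)
  phen <- toy$bat[toy$bat$subject_id %in% ids, ]
  sc2 <- matrix(rnorm(nrow(phen) * 2), ncol = 2)
  des2 <- build_design(phen, sc2)
  expect_equal(des2$subject, rep(1:20, each = 3))
  expect_equal(unname(des2$X[, "Session"]), rep(1:3, 20))
  expect_equal(unname(des2$X[, "SexFemale"]),
               as.numeric(phen$sex == "female"))

  # missing cells are reported
  phen_bad <- phen; phen_bad$accel[2] <- NA
  expect_error(build_design(phen_bad, sc2), "missing cells")
})

test_that("posterior_p implements the two-tailed doubling rule", {
  expect_equal(posterior_p(c(1, 2, 3, -1)), 0.5)
  expect_equal(posterior_p(c(1, 2, 3)), 0)
  expect_equal(posterior_p(c(0, 0, 1)), 0)   # zeros count to neither side
  set.seed(31)
  expect_lt(abs(posterior_p(rnorm(10000)) - 1), 0.03)
  expect_error(posterior_p(numeric(0)), "empty")
})

test_that("fdr_adjust reproduces hand-applied BH and its properties", {
  # hand-applied step-up: sorted (0.01, 0.02, 0.04, 0.8) ->
  # (0.04, 0.04, 0.0533..., 0.8)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04, 0.8)),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.8))
  # published posterior p-values survive alpha = 0.05
  adj <- fdr_adjust(c(0.007, 0.004, 0.009, 0.009))
  expect_lte(max(adj), 0.05)
  # single p unchanged; order-invariant; adjusted >= raw; the adjusted
  # vector is a fixed point of the monotonicity (step-up minimum) correction
  expect_equal(fdr_adjust(0.03), 0.03)
  p <- c(0.3, 0.01, 0.2, 0.04, 0.9)
  adj <- fdr_adjust(p)
  o_sort <- order(p)
  expect_true(!is.unsorted(adj[o_sort]))
  expect_equal(adj[o_sort], rev(cummin(rev(adj[o_sort]))))
  o <- sample(seq_along(p))
  expect_equal(fdr_adjust(p[o]), fdr_adjust(p)[o])
  expect_true(all(fdr_adjust(p) >= p))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the Gaussian limit matches the closed-form ridge/OLS oracle", {
  set.seed(32)
  n <- 2000
  X <- cbind(1, scale(matrix(rnorm(n * 3), n, 3)))
  colnames(X) <- c("(Intercept)", "a", "b", "c")
  y <- as.numeric(X %*% c(0.3, -0.4, 0.2, 0) + rnorm(n, 0, 0.8))
  des <- list(Y = matrix(y, dimnames = list(NULL, "resp")), X = X,
              subject = NULL, session = NULL)
  fit <- fit_bhm(des, sampler_config(chains = 2, iter = 1500, warmup = 500,
                                     seed = 7),
                 ranef = FALSE, nu_fixed = Inf)
  expect_true(fit$converged)
  d <- bhm_draws(fit, "^beta\\[")
  mcse <- apply(d, 2, sd) / sqrt(as.numeric(coda::effectiveSize(coda::mcmc(d))))
  ols <- qr.coef(qr(X), y)
  expect_true(all(abs(colMeans(d) - ols) < 2.5 * mcse + 1e-3))
})

test_that("under a null generator the accel credible intervals cover zero", {
  covered <- 0L; total <- 0L
  for (s in 1:4) {
    co <- generate_cohort(cohort_config(n_subjects = 120, n_fmri = 0),
                          seed = 400 + s)
    eff <- effect_config(beta_accel = rep(0, 4), beta_age = rep(0, 4),
                         beta_session = rep(0, 4))
    bat <- generate_cognitive_battery(co, eff, seed = 500 + s)
    f <- attr(bat, "latent_factors")
    des <- build_design(bat, scale(f))
    fit <- fit_bhm(des, sampler_config(chains = 2, iter = 800, warmup = 400,
                                       seed = s))
    su <- summary(fit, allow_nonconverged = TRUE)
    acc <- su[su$term == "AgeAccelGrim", ]
    covered <- covered + sum(acc$ci_lower <= 0 & acc$ci_upper >= 0)
    total <- total + nrow(acc)
  }
  expect_gte(covered / total, 0.9)
})

test_that("inference is refused on a deliberately short chain", {
  set.seed(33)
  n <- 80
  X <- cbind(1, rnorm(n)); colnames(X) <- c("(Intercept)", "a")
  y <- as.numeric(X %*% c(0, 0.5) + rnorm(n))
  des <- list(Y = matrix(y, dimnames = list(NULL, "resp")), X = X,
              subject = NULL, session = NULL)
  fit <- fit_bhm(des, sampler_config(chains = 2, iter = 40, warmup = 20,
                                     seed = 1), ranef = FALSE)
  expect_false(fit$converged)
  expect_error(summary(fit), "convergence contract")
  expect_error(posterior_predictive_check(fit), "convergence contract")
  expect_s3_class(summary(fit, allow_nonconverged = TRUE), "bhm_summary")
})

test_that("posterior predictive checks calibrate and flag a planted outlier", {
  set.seed(34)
  n <- 400
  X <- cbind(1, rnorm(n)); colnames(X) <- c("(Intercept)", "a")
  y <- as.numeric(X %*% c(0, 0.5) + rnorm(n, 0, 0.5))
  des <- list(Y = matrix(y, dimnames = list(NULL, "resp")), X = X,
              subject = NULL, session = NULL)
  fit <- fit_bhm(des, sampler_config(chains = 2, iter = 1000, warmup = 500,
                                     seed = 2), ranef = FALSE, nu_fixed = Inf)
  pp <- posterior_predictive_check(fit, allow_nonconverged = TRUE)
  expect_equal(attr(pp, "n_rep"), 1000L)   # one replicate per kept draw
  calib <- pp[pp$statistic %in% c("mean", "sd"), "p_tail"]
  expect_true(all(calib > 0.05 & calib < 0.95))

  # inject a 10-sigma outlier; the extreme-value statistic flags misfit
  y_out <- y
  y_out[1] <- y_out[1] + 10 * 0.5
  des$Y[, 1] <- y_out
  fit2 <- fit_bhm(des, sampler_config(chains = 2, iter = 1000, warmup = 500,
                                      seed = 2), ranef = FALSE, nu_fixed = Inf)
  pp2 <- posterior_predictive_check(fit2, allow_nonconverged = TRUE)
  expect_lt(pp2[pp2$statistic == "max", "p_tail"], 0.05)
})
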
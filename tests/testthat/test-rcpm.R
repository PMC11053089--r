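test_that("residualization matches hand-solved least squares", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 3, 5)
  rp <- residualize(y, cbind(x = x))
  # hand-solved normal equations: slope 1.3, intercept -0.5
  expect_equal(unname(rp$coefficients), c(-0.5, 1.3))
  expect_equal(rp$residuals, y - (-0.5 + 1.3 * x))

  # y = confound -> zero residuals
  expect_lt(max(abs(residualize(x, cbind(x))$residuals)), 1e-12)

  # confound orthogonal to the centered response leaves it unchanged
  y2 <- c(-1, 1, -1, 1, -1, 1)
  cf <- c(1, 1, 2, 2, 3, 3)
  expect_equal(residualize(y2, cbind(cf))$residuals, y2)

  # rank deficiency names the collinear columns
  expect_error(residualize(rnorm(10), cbind(a = 1:10, b = 2 * (1:10))), "b")
})

test_that("ridge_solve agrees with the explicit solve and across forms", {
  X <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2)
  y <- c(1, 2, 3)
  fit <- ridge_solve(X, y, lambda = 1)
  Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  direct <- solve(crossprod(Xc) + diag(1, 2), crossprod(Xc, yc))
  expect_lt(max(abs(fit$beta - direct)), 1e-10)
  expect_equal(fit$intercept, 2)

  # infinite-shrinkage limit: coefficients to 0, predictions to mean(y)
  big <- ridge_solve(X, y, lambda = 1e12)
  expect_lt(max(abs(big$beta)), 1e-9)

  # primal and dual agree on p >> n problems
  set.seed(41)
  Xw <- matrix(rnorm(20 * 500), 20, 500)
  yw <- rnorm(20)
  for (lam in c(0.1, 10, 1000)) {
    bp <- ridge_solve(Xw, yw, lam, form = "primal")$beta
    bd <- ridge_solve(Xw, yw, lam, form = "dual")$beta
    expect_lt(max(abs(bp - bd)), 1e-8)
  }
  expect_error(ridge_solve(X, y, lambda = 0), "positive")
})

test_that("nested CV recovers planted signal and stays null under noise", {
  set.seed(42)
  n <- 60
  y <- rnorm(n)
  # planted perfect signal in one column, tiny lambda available (the noise
  # block is kept weaker than the plant: ridge shrinks, it does not select)
  edges <- cbind(y, matrix(rnorm(n * 30, 0, 0.3), n, 30))
  cfg <- rcpm_config(outer_k = 5, n_repeats = 3, inner_k = 2,
                     lambda_grid = 10^seq(-4, 2, length.out = 20), seed = 1)
  run <- nested_cv_predict(edges, y, cfg)
  expect_gt(run$median_rho, 0.95)
  expect_equal(length(run$rho), 3L)
  expect_equal(dim(run$predictions), c(n, 3L))

  # pure noise edges: performance near zero
  edges0 <- matrix(rnorm(98 * 500), 98, 500)
  y0 <- rnorm(98)
  run0 <- nested_cv_predict(edges0, y0,
                            rcpm_config(n_repeats = 3, seed = 2))
  expect_lt(abs(run0$median_rho), 0.15)

  expect_error(nested_cv_predict(edges[1:10, ], y[1:10],
                                 rcpm_config(outer_k = 10)), "< 2 subjects")
})

test_that("the CV pipeline is invariant to affine rescaling of the phenotype", {
  set.seed(43)
  n <- 50
  edges <- matrix(rnorm(n * 100), n, 100)
  y <- edges[, 1] + rnorm(n)
  cfg <- rcpm_config(outer_k = 5, n_repeats = 2, seed = 9)
  r1 <- nested_cv_predict(edges, y, cfg, collect_coefficients = FALSE)
  r2 <- nested_cv_predict(edges, 3 * y + 10, cfg, collect_coefficients = FALSE)
  expect_equal(r1$rho, r2$rho, tolerance = 1e-10)
})

test_that("lambda tuning never touches held-out subjects", {
  # perturbation probe: corrupt the held-out rows arbitrarily; the selected
  # penalties and the training-fold model must not change
  set.seed(44)
  n <- 40
  edges <- matrix(rnorm(n * 60), n, 60)
  y <- rnorm(n)
  train <- 1:30
  test <- 31:40
  K <- tcrossprod(edges)
  lam1 <- withr::with_seed(5, epiconn:::.select_lambda(
    K, train, y, 10^seq(-2, 3, length.out = 10), inner_k = 2))
  edges2 <- edges
  edges2[test, ] <- matrix(rnorm(10 * 60, 50, 100), 10, 60)
  y2 <- y
  y2[test] <- y2[test] * 1000
  K2 <- tcrossprod(edges2)
  lam2 <- withr::with_seed(5, epiconn:::.select_lambda(
    K2, train, y2, 10^seq(-2, 3, length.out = 10), inner_k = 2))
  expect_identical(lam1, lam2)
})

test_that("permutation counting follows the published convention", {
  null <- seq(0.1, 1.0, by = 0.1)
  expect_equal(perm_pvalue(null, 0.55), 0.5)
  expect_equal(perm_pvalue(null, 2), 0)            # p = 0 possible
  expect_equal(perm_pvalue(null, 2, smoothing = TRUE), 1 / 11)
  expect_equal(perm_pvalue(null, 0), 1)
})

test_that("permutation p-values are roughly uniform under the null", {
  set.seed(45)
  cfg <- rcpm_config(outer_k = 4, n_repeats = 1, inner_k = 2,
                     lambda_grid = 10^seq(-1, 3, length.out = 8),
                     perm_iters = 19)
  pvals <- vapply(1:30, function(s) {
    set.seed(1000 + s)
    edges <- matrix(rnorm(36 * 50), 36, 50)
    y <- rnorm(36)
    cfg$seed <- s
    obs <- nested_cv_predict(edges, y, cfg,
                             collect_coefficients = FALSE)$median_rho
    permutation_test(edges, y, cfg, obs)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.25)
})

test_that("coefficient collection splits signs with disjoint support", {
  v1 <- c(1, -2, 0)
  v2 <- c(3, 0, 0)
  co <- collect_coefficients(list(v1, v2), n_nodes = 3)
  expect_equal(co$mean_vector, c(2, -1, 0))
  tab <- edge_index_table(3)
  expect_equal(co$positive[tab$i[1], tab$j[1]], 2)
  expect_equal(co$negative[tab$i[2], tab$j[2]], 1)
  expect_true(all(co$positive * co$negative == 0))
  expect_identical(co$positive, t(co$positive))

  # single fold: average equals that fold's vector
  expect_equal(collect_coefficients(list(v1), 3)$mean_vector, v1)
})

test_that("rcpm wrapper ties the stages together on planted signal", {
  set.seed(46)
  n <- 50; n_nodes <- 20
  meta_edges <- n_nodes * (n_nodes - 1) / 2
  y <- rnorm(n)
  conf <- cbind(age = rnorm(n))
  edges <- matrix(rnorm(n * meta_edges, 0.2, 0.2), n, meta_edges)
  edges[, 1:10] <- 0.2 + 0.2 * (0.7 * scale(y)[, 1] +
                                  sqrt(1 - 0.49) * matrix(rnorm(n * 10), n))
  fit <- rcpm(edges, y, confounds = conf,
              config = rcpm_config(outer_k = 5, n_repeats = 3,
                                   perm_iters = 39, seed = 3),
              permutation = TRUE)
  expect_s3_class(fit, "rcpm")
  expect_gt(fit$median_rho, 0.3)
  expect_lte(fit$p, 0.1)
  expect_equal(dim(fit$coefficients$positive), c(n_nodes, n_nodes))
})
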
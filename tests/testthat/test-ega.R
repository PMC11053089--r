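test_that("glasso matches an independent convex-optimization oracle", {
  # data shaped by a known tridiagonal precision structure
  Theta_true <- matrix(c(2, -1, 0, -1, 2, -1, 0, -1, 2), 3, 3)
  set.seed(11)
  X <- MASS::mvrnorm(400, rep(0, 3), solve(Theta_true))
  S <- cor(X)
  for (lam in c(0.02, 0.1, 0.3)) {
    fit <- epiconn:::.glasso_fit(S, lam)
    oracle <- admm_glasso(S, lam)
    expect_lt(max(abs(fit$Theta - oracle)), 1e-5)
  }
  # a p = 5 instance
  set.seed(12)
  X5 <- matrix(rnorm(300 * 5), 300, 5)
  X5[, 2] <- X5[, 1] + rnorm(300)
  S5 <- cor(X5)
  fit5 <- epiconn:::.glasso_fit(S5, 0.1)
  expect_lt(max(abs(fit5$Theta - admm_glasso(S5, 0.1))), 1e-5)
})

test_that("independent items give an empty selected network", {
  set.seed(13)
  X <- matrix(rnorm(3000 * 10), 3000, 10)
  g <- fit_glasso_network(X)
  expect_true(all(abs(g$W[upper.tri(g$W)]) == 0))
})

test_that("the default battery yields a 4-block partial-correlation network", {
  fx <- default_battery()
  g <- fit_glasso_network(session_mean_items(fx$battery))
  items <- battery_items()
  memb <- rep(seq_along(items), lengths(items))
  W <- abs(g$W)
  within <- W[outer(memb, memb, "==") & upper.tri(W)]
  between <- W[outer(memb, memb, "!=") & upper.tri(W)]
  expect_gt(mean(within), mean(between))
  expect_error(fit_glasso_network(matrix(rnorm(6), 3, 2)), "at least 4")
})

test_that("community detection finds planted structure and brute-force optima", {
  # two disconnected 3-cliques
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1; diag(A) <- 0
  cm <- detect_communities(A, seed = 1)
  expect_equal(cm$n_communities, 2L)
  expect_equal(unname(cm$membership), c(1L, 1L, 1L, 2L, 2L, 2L))

  # weighted toys: Louvain modularity equals the exhaustive-search maximum
  # (genuine local optima are flagged, not failed; record the rate)
  misses <- 0L
  for (s in 1:6) {
    set.seed(s)
    p <- sample(5:8, 1)
    W <- matrix(runif(p * p), p, p); W <- (W + t(W)) / 2; diag(W) <- 0
    W[W < 0.5] <- 0
    if (all(W == 0)) next
    cm <- detect_communities(W, seed = s)
    best <- brute_force_modularity(W)
    if (cm$modularity < best - 1e-9) misses <- misses + 1L
    expect_gte(cm$modularity, best - 0.05)
  }
  expect_lte(misses, 2L)

  # empty graph: singleton communities with a warning
  expect_warning(cm0 <- detect_communities(matrix(0, 4, 4)), "empty")
  expect_equal(cm0$n_communities, 4L)
})

test_that("EGA detects four communities on the default battery", {
  fx <- default_battery()
  e <- ega(session_mean_items(fx$battery), seed = 1)
  expect_s3_class(e, "ega")
  expect_equal(e$communities$n_communities, 4L)
  # walktrap cross-check agrees on the partition
  wt <- detect_communities(e$graph, method = "walktrap")
  expect_equal(length(unique(paste(e$communities$membership,
                                   wt$membership))), 4L)
})

test_that("boot_ega with one replicate returns that replicate's network", {
  X <- make_block_data(150, c(3, 3), seed = 21)
  be <- boot_ega(X, n_boot = 1, seed = 5)
  expect_equal(dim(be$W_med), c(6L, 6L))
  # the median of one replicate has the replicate's exact sparsity pattern
  expect_true(all(be$item_stability >= 0 & be$item_stability <= 1))
  expect_true(all(rowSums(be$item_stability) <= 1 + 1e-12))
})

test_that("well-separated blocks give perfect item stability", {
  X <- make_block_data(400, c(3, 3, 3), r_within = 0.75, seed = 22)
  be <- boot_ega(X, n_boot = 25, seed = 6)
  expect_equal(be$typical$n_communities, 3L)
  own <- be$item_stability[cbind(seq_len(9), be$typical$membership)]
  expect_true(all(own == 1))
})

test_that("network scores follow the loading rule and the toy hand-worked case", {
  # 4 items, two 2-item communities, within-community |w| = 0.5
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.5
  W[3, 4] <- W[4, 3] <- 0.5
  colnames(W) <- rownames(W) <- paste0("it", 1:4)
  set.seed(23)
  X <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, colnames(W)))
  comm <- structure(list(membership = setNames(c(1L, 1L, 2L, 2L), colnames(W)),
                         n_communities = 2L, modularity = NA, method = "louvain"),
                    class = "community_solution")
  ns <- network_scores(X, W, comm)
  expect_equal(unname(ns$weights[1:2, 1]), c(0.5, 0.5))
  # hand computation: standardized mean of the two z-items
  z <- scale(X)
  hand <- 0.5 * z[, 1] + 0.5 * z[, 2]
  hand <- (hand - mean(hand)) / sd(hand)
  expect_equal(unname(ns$scores[, 1]), unname(hand), tolerance = 1e-12)
  expect_equal(unname(colMeans(ns$scores)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(ns$scores, 2, sd)), c(1, 1), tolerance = 1e-12)
  # empty community errors
  comm_bad <- comm; comm_bad$membership[] <- 1L; comm_bad$n_communities <- 2L
  expect_error(network_scores(X, W, comm_bad), "empty community")
})

test_that("scores are invariant to item order up to community relabeling", {
  fx <- default_battery()
  X <- session_mean_items(fx$battery)
  e <- ega(X, seed = 1)
  ns <- network_scores(X, e$graph$W, e$communities)
  perm <- rev(seq_len(ncol(X)))
  e2 <- ega(X[, perm], seed = 1)
  ns2 <- network_scores(X[, perm], e2$graph$W, e2$communities)
  # match columns by anchor item community membership
  for (k in seq_len(4)) {
    anchor <- names(which(e$communities$membership == k))[1]
    k2 <- e2$communities$membership[[anchor]]
    expect_gt(abs(cor(ns$scores[, k], ns2$scores[, k2])), 0.999)
  }
})

test_that("scores correlate most with their own community's items", {
  fx <- default_battery()
  X <- session_mean_items(fx$battery)
  e <- ega(X, seed = 1)
  ns <- network_scores(X, e$graph$W, e$communities)
  memb <- e$communities$membership
  for (k in seq_len(4)) {
    own <- mean(cor(ns$scores[, k], X[, memb == k]))
    other <- mean(cor(ns$scores[, k], X[, memb != k]))
    expect_gt(own, other)
  }
})

test_that("eigenvalue heuristic handles exact and block correlation matrices", {
  expect_equal(eigenvalue_heuristic(diag(15)), 0L)

  # 4 compound-symmetric blocks of 3 items at r = 0.6: eigenvalues are
  # 1 + 2r = 2.2 (x4) and 1 - r = 0.4 (x8), so exactly 4 exceed 1
  R <- matrix(0, 12, 12)
  for (b in 0:3) {
    idx <- b * 3 + 1:3
    R[idx, idx] <- 0.6
  }
  diag(R) <- 1
  expect_equal(eigenvalue_heuristic(R), 4L)

  fx <- default_battery()
  expect_equal(eigenvalue_heuristic(session_mean_items(fx$battery)), 4L)
})

test_that("marginal correlation report matches hand-computed aggregation", {
  # two subjects x two sessions, hand-checkable numbers
  phen <- data.frame(
    subject_id = c("a", "a", "b", "b"),
    session = c(1, 2, 1, 2),
    DigSym = c(1, 3, 2, 6), Recall = c(2, 2, 1, 5),
    accel = c(1, 1, -1, -1), age = c(60, 60, 70, 70))
  rep <- marginal_correlation_report(phen)
  # session means: DigSym (2, 4), Recall (2, 3)
  expect_equal(rep["DigSym", "accel"], cor(c(2, 4), c(1, -1)))
  expect_equal(rep["DigSym", "Recall"], 1)
  expect_equal(rep["DigSym", "age"], cor(c(2, 4), c(60, 70)))

  fx <- default_battery()
  X <- session_mean_items(fx$battery)
  e <- ega(X, seed = 1)
  sc <- network_scores(as.matrix(fx$battery[, item_names()]),
                       e$graph$W, e$communities)
  rep2 <- marginal_correlation_report(fx$battery, sc)
  expect_lt(abs(rep2["accel", "age"]), 1e-10)
  it <- item_names()
  expect_true(all(rep2[it, it] > 0))
})
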
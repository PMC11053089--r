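# Shared fixtures, generated in code.

# small default cohort + battery, cached per test run
default_battery <- local({
  cache <- NULL
  function(seed = 1L) {
    if (is.null(cache)) {
      co <- generate_cohort(cohort_config(), seed = seed)
      bat <- generate_cognitive_battery(co, effect_config(), seed = seed + 1L)
      cache <<- list(cohort = co, battery = bat)
    }
    cache
  }
})

item_names <- function() unlist(battery_items(), use.names = FALSE)

session_mean_items <- function(bat) {
  agg <- aggregate(bat[, item_names()],
                   by = list(subject_id = bat$subject_id), FUN = mean)
  as.matrix(agg[, item_names()])
}

# independent ADMM solver for the graphical-lasso objective
#   min_{Theta > 0}  -log det Theta + tr(S Theta) + lambda * |offdiag(Theta)|_1
# used as a convex-optimization oracle on small problems
admm_glasso <- function(S, lambda, rho = 1, iters = 5000, tol = 1e-9) {
  p <- ncol(S)
  Theta <- diag(p); Z <- diag(p); U <- matrix(0, p, p)
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  for (i in seq_len(iters)) {
    eg <- eigen(rho * (Z - U) - S, symmetric = TRUE)
    dvals <- (eg$values + sqrt(eg$values^2 + 4 * rho)) / (2 * rho)
    Theta <- eg$vectors %*% (dvals * t(eg$vectors))
    Z_old <- Z
    A <- Theta + U
    Z <- soft(A, lambda / rho)
    diag(Z) <- diag(A)            # diagonal unpenalized
    U <- U + Theta - Z
    if (max(abs(Z - Z_old)) < tol && max(abs(Theta - Z)) < tol) break
  }
  (Z + t(Z)) / 2
}

# exhaustive modularity maximization over all set partitions (p <= 8)
brute_force_modularity <- function(A) {
  p <- ncol(A)
  m2 <- sum(A)                                # 2m for weighted graphs
  deg <- rowSums(A)
  best <- -Inf
  part <- integer(p)
  # iterate over restricted growth strings (set partitions)
  recurse <- function(i, maxl) {
    if (i > p) {
      Q <- 0
      for (k in seq_len(maxl)) {
        idx <- which(part[1:p] == k)
        Q <- Q + sum(A[idx, idx]) / m2 - (sum(deg[idx]) / m2)^2
      }
      if (Q > best) best <<- Q
      return(invisible())
    }
    for (k in seq_len(maxl + 1L)) {
      part[i] <<- k
      recurse(i + 1L, max(maxl, k))
    }
  }
  recurse(1L, 0L)
  best
}

# block-structured multivariate data with known communities
make_block_data <- function(n, block_sizes, r_within = 0.7, r_between = 0,
                            seed = 1) {
  set.seed(seed)
  p <- sum(block_sizes)
  R <- matrix(r_between, p, p)
  at <- 1L
  for (b in block_sizes) {
    idx <- at:(at + b - 1L)
    R[idx, idx] <- r_within
    at <- at + b
  }
  diag(R) <- 1
  MASS::mvrnorm(n, rep(0, p), R)
}
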
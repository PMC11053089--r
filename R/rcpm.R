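#' Configuration for ridge connectome-based predictive modeling
#'
#' Defaults follow the published procedure: 100 repeats of outer 10-fold
#' cross-validation with an inner 2-fold loop tuning the ridge penalty, and
#' a 1000-iteration permutation null. The penalty grid (unspecified in the
#' source procedure) is 50 log-spaced values in `[1e-2, 1e5]`; the inner
#' tuning criterion is mean squared error.
#'
#' @param outer_k outer folds (>= 2).
#' @param n_repeats repeats of the outer loop.
#' @param inner_k inner folds for penalty tuning.
#' @param lambda_grid positive ridge penalties.
#' @param perm_iters permutation iterations.
#' @param seed integer seed.
#' @return List of class `rcpm_config`.
#' @export
rcpm_config <- function(outer_k = 10L, n_repeats = 100L, inner_k = 2L,
                        lambda_grid = 10^seq(-2, 5, length.out = 50),
                        perm_iters = 1000L, seed = 1L) {
  outer_k <- .check_count(outer_k, "outer_k", min = 2L)
  if (any(lambda_grid <= 0)) {
    stop("invalid config: all lambda must be positive", call. = FALSE)
  }
  structure(list(outer_k = outer_k,
                 n_repeats = .check_count(n_repeats, "n_repeats"),
                 inner_k = .check_count(inner_k, "inner_k", min = 2L),
                 lambda_grid = sort(as.numeric(lambda_grid)),
                 perm_iters = .check_count(perm_iters, "perm_iters"),
                 seed = as.integer(seed)), class = "rcpm_config")
}

#' Residualize a phenotype on confound variables
#'
#' Ordinary least squares of the phenotype on an intercept plus the confound
#' columns; the residuals (orthogonal to every confound and the intercept)
#' are the prediction target of the connectome models.
#'
#' @param y numeric phenotype vector.
#' @param confounds n x k numeric matrix or data.frame (may be NULL/empty).
#' @return Object of class `residualized_phenotype`: list with `residuals`,
#'   `coefficients`, `confound_names`.
#' @export
residualize <- function(y, confounds = NULL) {
  y <- as.numeric(y)
  if (is.null(confounds) || NCOL(confounds) == 0L) {
    X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    cf <- as.matrix(as.data.frame(confounds))
    if (nrow(cf) != length(y)) stop("confound rows do not match y", call. = FALSE)
    X <- cbind("(Intercept)" = 1, cf)
  }
  if (length(y) <= ncol(X)) stop("need n > k + 1 observations", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("collinear confound column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  fit <- lm.fit(X, y)
  structure(list(residuals = as.numeric(fit$residuals),
                 coefficients = fit$coefficients,
                 confound_names = setdiff(colnames(X), "(Intercept)")),
            class = "residualized_phenotype")
}

#' Ridge regression with an unpenalized intercept
#'
#' Minimizes `||y - X b - b0||^2 + lambda ||b||^2`. The predictors are
#' mean-centered so the intercept is the training mean of `y`. When
#' `p > n` (the 35,778-edge regime) the solution is computed in the dual
#' (kernel) form, `b = X' (XX' + lambda I)^{-1} y_c`, so the cost scales
#' with n rather than p; the primal normal equations are used otherwise.
#' Both forms are exact and agree to numerical precision.
#'
#' @param X n x p predictor matrix.
#' @param y numeric response.
#' @param lambda positive ridge penalty.
#' @param form "auto" (default), "primal", or "dual".
#' @return List with `beta` (length p), `intercept`, `x_center`.
#' @export
ridge_solve <- function(X, y, lambda, form = c("auto", "primal", "dual")) {
  form <- match.arg(form)
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  xc <- colMeans(X)
  Xc <- sweep(X, 2, xc)
  yc <- y - mean(y)
  if (form == "auto") form <- if (p > n) "dual" else "primal"
  if (form == "primal") {
    beta <- solve(crossprod(Xc) + diag(lambda, p), crossprod(Xc, yc))
  } else {
    alpha <- solve(tcrossprod(Xc) + diag(lambda, n), yc)
    beta <- crossprod(Xc, alpha)
  }
  list(beta = as.numeric(beta), intercept = mean(y), x_center = xc)
}

# centered Gram submatrix: K_c[i, j] = (x_i - m_T)'(x_j - m_T) for training
# means m_T, computed from the raw Gram by double-centering over train rows
.center_gram <- function(K, rows, cols, train) {
  ci <- rowMeans(K[rows, train, drop = FALSE])
  cj <- rowMeans(K[cols, train, drop = FALSE])
  cbar <- mean(K[train, train])
  K[rows, cols, drop = FALSE] - outer(ci, rep(1, length(cols))) -
    outer(rep(1, length(rows)), cj) + cbar
}

# seeded fold assignment: uniform shuffle, sizes differing by at most 1
.make_folds <- function(n, k) {
  if (n < 2L * k) stop("fold with < 2 subjects: n too small for k folds",
                       call. = FALSE)
  sample(rep_len(seq_len(k), n))
}

# dual-form ridge predictions for all lambdas at once via eigendecomposition
# of the centered training Gram; returns a length(lambda) x n_test matrix
.dual_predict_path <- function(K, train, test, y, lambdas) {
  Kt <- .center_gram(K, train, train, train)
  Kx <- .center_gram(K, test, train, train)
  eg <- eigen(Kt, symmetric = TRUE)
  ytr <- y[train] - mean(y[train])
  vy <- crossprod(eg$vectors, ytr)
  preds <- matrix(0, length(lambdas), length(test))
  for (li in seq_along(lambdas)) {
    alpha <- eg$vectors %*% (vy / (pmax(eg$values, 0) + lambdas[li]))
    preds[li, ] <- Kx %*% alpha + mean(y[train])
  }
  preds
}

# inner-CV lambda selection by mean squared error, using training rows only
.select_lambda <- function(K, train, y, lambdas, inner_k) {
  folds <- .make_folds(length(train), inner_k)
  sse <- numeric(length(lambdas))
  for (f in seq_len(inner_k)) {
    tr <- train[folds != f]
    te <- train[folds == f]
    preds <- .dual_predict_path(K, tr, te, y, lambdas)
    sse <- sse + rowSums(sweep(preds, 2, y[te])^2)
  }
  lambdas[which.min(sse)]   # ties: smallest penalty index
}

#' Nested cross-validated ridge prediction of a phenotype from edges
#'
#' Per repeat: subjects are shuffled into `outer_k` folds; within each
#' training fold the ridge penalty is chosen by inner `inner_k`-fold mean
#' squared error (held-out subjects are never touched during tuning), the
#' model is refit on the full training fold in dual form, and held-out
#' predictions are recorded. Repeat performance is the Spearman correlation
#' between out-of-fold predictions and the observed phenotype over all
#' subjects; repeats are aggregated by the median. Edge features are
#' mean-centered with training-fold statistics only.
#'
#' @param edges n x p edge matrix (rows = subjects).
#' @param y_resid residualized phenotype (numeric vector or
#'   `residualized_phenotype`).
#' @param config an [rcpm_config()].
#' @param collect_coefficients accumulate the mean primal coefficient
#'   vector across all folds and repeats (skipped inside permutations).
#' @return Object of class `rcpm_cv`: `rho` (per-repeat Spearman),
#'   `median_rho`, `predictions` (n x n_repeats), `mean_coefficients`
#'   (length-p vector or NULL), `lambda_selected` (repeats x outer_k),
#'   `config`.
#' @export
nested_cv_predict <- function(edges, y_resid, config = rcpm_config(),
                              collect_coefficients = TRUE) {
  stopifnot(inherits(config, "rcpm_config"))
  y <- if (inherits(y_resid, "residualized_phenotype")) y_resid$residuals
       else as.numeric(y_resid)
  edges <- as.matrix(edges)
  n <- nrow(edges)
  if (length(y) != n) stop("edges and phenotype are not aligned", call. = FALSE)
  if (n < 2L * config$outer_k) {
    stop("fold with < 2 subjects: need n >= 2 * outer_k", call. = FALSE)
  }
  set.seed(config$seed)
  K <- tcrossprod(edges)
  lambdas <- config$lambda_grid

  preds <- matrix(NA_real_, n, config$n_repeats)
  rho <- numeric(config$n_repeats)
  lam_sel <- matrix(NA_real_, config$n_repeats, config$outer_k)
  coef_sum <- if (collect_coefficients) numeric(ncol(edges)) else NULL
  n_models <- 0L

  for (rep_i in seq_len(config$n_repeats)) {
    folds <- .make_folds(n, config$outer_k)
    for (f in seq_len(config$outer_k)) {
      test <- which(folds == f)
      train <- which(folds != f)
      lam <- .select_lambda(K, train, y, lambdas, config$inner_k)
      lam_sel[rep_i, f] <- lam
      Kt <- .center_gram(K, train, train, train)
      alpha <- solve(Kt + diag(lam, length(train)),
                     y[train] - mean(y[train]))
      Kx <- .center_gram(K, test, train, train)
      preds[test, rep_i] <- Kx %*% alpha + mean(y[train])
      if (collect_coefficients) {
        Xc <- sweep(edges[train, , drop = FALSE], 2,
                    colMeans(edges[train, , drop = FALSE]))
        coef_sum <- coef_sum + as.numeric(crossprod(Xc, alpha))
        n_models <- n_models + 1L
      }
    }
    rho[rep_i] <- cor(preds[, rep_i], y, method = "spearman")
  }

  structure(list(rho = rho, median_rho = median(rho), predictions = preds,
                 mean_coefficients = if (collect_coefficients) coef_sum / n_models,
                 lambda_selected = lam_sel, config = config),
            class = "rcpm_cv")
}

#' Non-parametric p-value from a permutation null
#'
#' `p = #\{null >= observed\} / length(null)` (the published counting
#' convention, under which p = 0 is possible), or the
#' `(count + 1) / (iters + 1)` smoothed variant.
#'
#' @param null_rho numeric vector of null performance values.
#' @param observed observed performance value.
#' @param smoothing use the add-one convention.
#' @return Probability in `[0, 1]`.
#' @export
perm_pvalue <- function(null_rho, observed, smoothing = FALSE) {
  ct <- sum(null_rho >= observed)
  if (smoothing) (ct + 1) / (length(null_rho) + 1) else ct / length(null_rho)
}

#' Permutation test of cross-validated prediction performance
#'
#' Permutes the residualized phenotype across subjects and reruns a
#' single-repeat nested-CV pipeline per iteration, building the null
#' distribution of the Spearman performance metric; the non-parametric
#' p-value counts how often the null meets or exceeds the observed median
#' performance.
#'
#' @inheritParams nested_cv_predict
#' @param observed_median_rho observed median Spearman from the real run.
#' @param perm_iters overrides `config$perm_iters` if given.
#' @param smoothing passed to [perm_pvalue()].
#' @return List with `null_rho`, `p`, `observed`.
#' @export
permutation_test <- function(edges, y_resid, config = rcpm_config(),
                             observed_median_rho, perm_iters = NULL,
                             smoothing = FALSE) {
  y <- if (inherits(y_resid, "residualized_phenotype")) y_resid$residuals
       else as.numeric(y_resid)
  iters <- if (is.null(perm_iters)) config$perm_iters else
    .check_count(perm_iters, "perm_iters")
  null_rho <- numeric(iters)
  for (b in seq_len(iters)) {
    set.seed(config$seed + 77000L + b)
    y_perm <- sample(y)
    cfg_b <- config
    cfg_b$n_repeats <- 1L
    cfg_b$seed <- config$seed + 154000L + b
    run <- nested_cv_predict(edges, y_perm, cfg_b,
                             collect_coefficients = FALSE)
    null_rho[b] <- run$median_rho
  }
  list(null_rho = null_rho,
       p = perm_pvalue(null_rho, observed_median_rho, smoothing),
       observed = observed_median_rho)
}

#' Split averaged fold coefficients into signed connectivity matrices
#'
#' Averages fold-level coefficient vectors (or takes the stored mean from a
#' fitted `rcpm_cv`), devectorizes to a symmetric matrix, and separates the
#' positive part and the (absolute-valued) negative part -- two nonnegative
#' symmetric matrices with disjoint supports, used for the region-importance
#' analyses.
#'
#' @param coefs an `rcpm_cv` object, a list/matrix of fold coefficient
#'   vectors, or a single mean coefficient vector.
#' @param n_nodes node count for devectorization.
#' @return List with `positive`, `negative` (nonnegative symmetric
#'   matrices) and `mean_vector`.
#' @export
collect_coefficients <- function(coefs, n_nodes) {
  v <- if (inherits(coefs, "rcpm_cv")) {
    if (is.null(coefs$mean_coefficients)) {
      stop("rcpm_cv was run without coefficient collection", call. = FALSE)
    }
    coefs$mean_coefficients
  } else if (is.list(coefs)) {
    Reduce(`+`, coefs) / length(coefs)
  } else if (is.matrix(coefs)) {
    colMeans(coefs)
  } else {
    as.numeric(coefs)
  }
  M <- devectorize_connectivity(v, n_nodes)
  list(positive = pmax(M, 0), negative = pmax(-M, 0), mean_vector = v)
}

#' Ridge connectome-based predictive modeling of one phenotype
#'
#' End-to-end convenience wrapper: residualize the phenotype on its
#' confounds, run repeated nested cross-validation, optionally run the
#' permutation test, and collect the averaged signed coefficient matrices.
#'
#' @param edges n x p edge matrix.
#' @param y phenotype vector (one value per imaged subject).
#' @param confounds confound matrix/data.frame for residualization.
#' @param config an [rcpm_config()].
#' @param permutation run the permutation test.
#' @param n_nodes node count (inferred from the edge count if NULL).
#' @return Object of class `rcpm` with `cv` (`rcpm_cv`), `residualized`,
#'   `coefficients` (signed matrix pair), `perm` (or NULL), `median_rho`,
#'   `p`.
#' @export
rcpm <- function(edges, y, confounds = NULL, config = rcpm_config(),
                 permutation = TRUE, n_nodes = NULL) {
  if (is.null(n_nodes)) {
    n_nodes <- as.integer(round((1 + sqrt(1 + 8 * ncol(edges))) / 2))
  }
  rp <- residualize(y, confounds)
  cv <- nested_cv_predict(edges, rp, config)
  co <- collect_coefficients(cv, n_nodes)
  perm <- if (permutation) {
    permutation_test(edges, rp, config, cv$median_rho)
  }
  structure(list(cv = cv, residualized = rp, coefficients = co,
                 perm = perm, median_rho = cv$median_rho,
                 p = if (!is.null(perm)) perm$p else NA_real_),
            class = "rcpm")
}

#' @export
print.rcpm <- function(x, ...) {
  cat("Ridge connectome-based predictive model\n")
  cat("  repeats: ", length(x$cv$rho), ", outer folds: ", x$cv$config$outer_k,
      ", inner folds: ", x$cv$config$inner_k, "\n", sep = "")
  cat("  median Spearman rho = ", round(x$median_rho, 3), "\n", sep = "")
  if (!is.null(x$perm)) {
    cat("  permutation p = ", signif(x$p, 3), " (",
        length(x$perm$null_rho), " iterations)\n", sep = "")
  }
  invisible(x)
}
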
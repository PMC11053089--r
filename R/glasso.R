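# Graphical lasso (coordinate descent) and EBIC penalty selection.
#
# Solves  max_Theta  log det(Theta) - tr(S Theta) - lambda * sum_{i!=j} |theta_ij|
# with the classic block-coordinate algorithm: each column of the working
# covariance W is updated by solving a lasso subproblem in covariance form.
# The diagonal is not penalized (w_ii = s_ii), the convention used by the
# EBIC-glasso networks of psychometric network analysis.

# one glasso fit at a single lambda; B holds per-column lasso coefficients
# (warm starts across the path); compiled coordinate-descent core
.glasso_fit <- function(S, lambda, B = NULL, W = NULL,
                        tol = 1e-6, max_sweep = 200L) {
  p <- ncol(S)
  if (is.null(W)) W <- S
  if (is.null(B)) B <- matrix(0, p - 1L, p)
  glasso_fit_cpp(S, lambda, B, W, tol, as.integer(max_sweep))
}

.ebic <- function(Theta, S, n, gamma) {
  p <- ncol(S)
  ll <- (n / 2) * (determinant(Theta, logarithm = TRUE)$modulus[1] -
                     sum(S * Theta))
  E <- sum(abs(Theta[upper.tri(Theta)]) > 0)
  -2 * ll + E * log(n) + 4 * gamma * E * log(p)
}

#' Regularized partial-correlation network of a set of items (EGA step)
#'
#' Estimates a sparse Gaussian graphical model over the item columns with
#' the graphical lasso, selecting the penalty by the extended Bayesian
#' information criterion, and converts the selected precision matrix to
#' partial correlations `w_ij = -theta_ij / sqrt(theta_ii * theta_jj)`.
#' Columns are standardized internally (the model is fit to the sample
#' correlation matrix). The penalty grid is `n_lambda` log-spaced values
#' from `lambda_max` (the largest absolute off-diagonal correlation, at
#' which the graph is empty) down to `lambda_min_ratio * lambda_max`.
#'
#' @param data n x p numeric item matrix (n >= 4).
#' @param gamma_ebic EBIC hyperparameter (default 0.5).
#' @param lambda_grid optional explicit penalty grid (decreasing).
#' @param n_lambda,lambda_min_ratio grid construction parameters.
#' @return An object of class `item_graph`: list with `W` (partial
#'   correlations, zero diagonal), `Theta`, `lambda`, `gamma`,
#'   `lambda_grid`, `ebic`, `n`, `item_names`.
#' @export
fit_glasso_network <- function(data, gamma_ebic = 0.5, lambda_grid = NULL,
                               n_lambda = 100L, lambda_min_ratio = 0.1) {
  data <- as.matrix(data)
  n <- nrow(data); p <- ncol(data)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  S <- cor(data)
  if (anyNA(S)) stop("constant item column: correlation undefined", call. = FALSE)
  if (is.null(lambda_grid)) {
    lam_max <- max(abs(S[upper.tri(S)]))
    if (lam_max <= 0) lam_max <- 1e-4
    lambda_grid <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                           length.out = n_lambda))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  best <- NULL; best_ebic <- Inf; B <- NULL; W <- NULL
  ebics <- numeric(length(lambda_grid))
  for (li in seq_along(lambda_grid)) {
    fit <- .glasso_fit(S, lambda_grid[li], B = B, W = W)
    B <- fit$B; W <- fit$W
    ebics[li] <- .ebic(fit$Theta, S, n, gamma_ebic)
    if (ebics[li] < best_ebic) {
      best_ebic <- ebics[li]
      best <- list(Theta = fit$Theta, lambda = lambda_grid[li])
    }
  }
  Theta <- best$Theta
  d <- sqrt(diag(Theta))
  Wpc <- -Theta / tcrossprod(d)
  diag(Wpc) <- 0
  nm <- colnames(data)
  if (!is.null(nm)) dimnames(Wpc) <- list(nm, nm)
  structure(list(W = Wpc, Theta = Theta, lambda = best$lambda,
                 gamma = gamma_ebic, lambda_grid = lambda_grid,
                 ebic = ebics, n = n, item_names = nm),
            class = "item_graph")
}

#' @export
print.item_graph <- function(x, ...) {
  p <- ncol(x$W)
  E <- sum(abs(x$W[upper.tri(x$W)]) > 0)
  cat("Regularized partial-correlation network (", p, " items)\n", sep = "")
  cat("  selected lambda = ", signif(x$lambda, 4),
      " (EBIC, gamma = ", x$gamma, ")\n", sep = "")
  cat("  nonzero edges: ", E, " / ", p * (p - 1) / 2, "\n", sep = "")
  invisible(x)
}
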
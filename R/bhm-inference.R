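#' Combined posterior draws of a fitted model
#'
#' @param fit a `bhm_fit`.
#' @param pars optional regular expression selecting parameter names.
#' @return Matrix of draws (all chains stacked) with parameter columns.
#' @export
bhm_draws <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "bhm_fit"))
  d <- do.call(rbind, fit$draws)
  if (!is.null(pars)) d <- d[, grepl(pars, colnames(d)), drop = FALSE]
  d
}

#' Two-tailed posterior probability of a coefficient
#'
#' The Bayesian analogue of a two-tailed p-value: twice the fraction of
#' posterior draws on the minority side of zero,
#' `p = 2 * min(#draws > 0, #draws < 0) / N`. Draws exactly at zero count
#' to neither side (a measure-zero event for continuous posteriors).
#'
#' @param draws numeric vector of posterior draws.
#' @return Probability in `[0, 1]`.
#' @export
posterior_p <- function(draws) {
  if (length(draws) == 0L) stop("empty draws", call. = FALSE)
  2 * min(sum(draws > 0), sum(draws < 0)) / length(draws)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values with monotonicity correction, as used for the
#' age-acceleration coefficients across the four cognitive domains.
#'
#' @param p_values vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

# MAP as the mode of a Silverman-bandwidth kernel density estimate
.map_estimate <- function(draws) {
  dens <- density(draws, bw = "nrd0")
  dens$x[which.max(dens$y)]
}

#' Posterior summary of the fixed effects
#'
#' One row per response x coefficient: MAP estimate (mode of a
#' Silverman-bandwidth kernel density over the marginal draws), posterior
#' median, central 95% credible interval, two-tailed posterior probability,
#' and -- for each coefficient across responses -- its BH
#' false-discovery-rate adjusted value. Convergence diagnostics are
#' enforced: a fit that misses the split R-hat < 1.01 / bulk ESS > 400
#' contract refuses summarization unless `allow_nonconverged = TRUE`.
#'
#' @param object a `bhm_fit`.
#' @param prob credible-interval mass (default 0.95).
#' @param allow_nonconverged override the convergence gate.
#' @param ... unused.
#' @return `data.frame` of class `bhm_summary`.
#' @export
summary.bhm_fit <- function(object, prob = 0.95, allow_nonconverged = FALSE,
                            ...) {
  if (!object$converged && !allow_nonconverged) {
    stop("fit did not meet the convergence contract (split R-hat < 1.01, ",
         "bulk ESS > 400); rerun with more iterations or pass ",
         "allow_nonconverged = TRUE to inspect anyway", call. = FALSE)
  }
  d <- bhm_draws(object, pars = "^beta\\[")
  alpha <- (1 - prob) / 2
  rows <- lapply(colnames(d), function(pn) {
    x <- d[, pn]
    parts <- sub("^beta\\[(.*),(.*)\\]$", "\\1|\\2", pn)
    parts <- strsplit(parts, "|", fixed = TRUE)[[1]]
    data.frame(response = parts[1], term = parts[2],
               map = .map_estimate(x), median = median(x),
               ci_lower = quantile(x, alpha), ci_upper = quantile(x, 1 - alpha),
               p = posterior_p(x),
               rhat = object$rhat[pn], ess = object$ess[pn])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_fdr <- NA_real_
  for (tm in unique(out$term)) {
    idx <- out$term == tm
    out$p_fdr[idx] <- fdr_adjust(out$p[idx])
  }
  class(out) <- c("bhm_summary", "data.frame")
  out
}

#' @export
print.bhm_fit <- function(x, ...) {
  cat("Hierarchical robust (Student-t) multivariate regression\n")
  cat("  responses: ", paste(x$response_names, collapse = ", "), "\n", sep = "")
  cat("  ", x$n, " observations",
      if (x$ranef) paste0(", ", x$n_subjects, " subjects (random intercept + session slope)"),
      "\n", sep = "")
  cat("  ", x$sampler$chains, " chains x ", x$sampler$iter, " iterations (",
      x$sampler$warmup, " warmup)\n", sep = "")
  b <- grepl("^beta", names(x$rhat))
  cat("  converged: ", x$converged,
      "  (coefficients: max R-hat ", round(max(x$rhat[b], na.rm = TRUE), 4),
      ", min ESS ", round(min(x$ess[b])),
      "; all parameters: max R-hat ", round(max(x$rhat, na.rm = TRUE), 4),
      ")\n", sep = "")
  invisible(x)
}

#' @export
coef.bhm_fit <- function(object, ...) {
  s <- summary(object, allow_nonconverged = TRUE)
  m <- matrix(s$map, nrow = length(unique(s$term)),
              dimnames = list(unique(s$term), unique(s$response)))
  m
}

#' Posterior predictive check
#'
#' Compares the observed per-response mean, SD, minimum and maximum with
#' their distributions over posterior-predictive replicated datasets (one
#' replicate per kept draw, generated inside the sampler conditional on the
#' drawn parameters and random effects). The reported tail probability is
#' `P(T_rep >= T_obs)`; values near 0 or 1 flag misfit of that statistic.
#'
#' @param fit a converged `bhm_fit`.
#' @param allow_nonconverged override the convergence gate.
#' @return `data.frame` with response, statistic, observed value, replicate
#'   mean, and tail probability; attribute `"n_rep"` holds the replicate
#'   count.
#' @export
posterior_predictive_check <- function(fit, allow_nonconverged = FALSE) {
  stopifnot(inherits(fit, "bhm_fit"))
  if (!fit$converged && !allow_nonconverged) {
    stop("fit did not meet the convergence contract; pass ",
         "allow_nonconverged = TRUE to inspect anyway", call. = FALSE)
  }
  rep_stats <- do.call(abind_first, fit$ppc)
  obs <- fit$observed_stats
  rows <- list()
  for (j in seq_along(fit$response_names)) {
    for (st in rownames(obs)) {
      reps <- rep_stats[, st, j]
      rows[[length(rows) + 1L]] <- data.frame(
        response = fit$response_names[j], statistic = st,
        observed = obs[st, j], replicated = mean(reps),
        p_tail = mean(reps >= obs[st, j]))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_rep") <- dim(rep_stats)[1]
  out
}

# stack 3-d arrays along the first dimension (kept draws across chains)
abind_first <- function(...) {
  arrs <- list(...)
  dims <- dim(arrs[[1]])
  total <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(NA_real_, c(total, dims[2], dims[3]),
               dimnames = c(list(NULL), dimnames(arrs[[1]])[2:3]))
  at <- 1L
  for (a in arrs) {
    out[at:(at + dim(a)[1] - 1L), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}
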
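#' Community detection on an item network
#'
#' Runs weighted modularity maximization on the absolute partial-correlation
#' network. Louvain (the default) is restarted `n_restarts` times under a
#' seeded RNG and the best-modularity partition is kept, ties broken by the
#' lexicographically smallest label vector; community labels are renumbered
#' contiguously by first appearance. Walktrap is available as a
#' deterministic cross-check.
#'
#' @param graph an `item_graph` from [fit_glasso_network()], or a symmetric
#'   weight matrix.
#' @param method "louvain" or "walktrap".
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed integer seed for the Louvain restarts.
#' @param n_restarts number of Louvain restarts (default 20).
#' @return An object of class `community_solution`: list with `membership`
#'   (named integer labels, contiguous 1..K), `n_communities`, `modularity`,
#'   `method`.
#' @export
detect_communities <- function(graph, method = c("louvain", "walktrap"),
                               resolution = 1, seed = 1L, n_restarts = 20L) {
  method <- match.arg(method)
  W <- if (inherits(graph, "item_graph")) graph$W else as.matrix(graph)
  p <- ncol(W)
  A <- abs(W)
  diag(A) <- 0
  nm <- colnames(A)
  if (is.null(nm)) nm <- paste0("V", seq_len(p))

  if (all(A == 0)) {
    warning("empty graph: every item assigned its own community")
    memb <- stats::setNames(seq_len(p), nm)
    return(structure(list(membership = memb, n_communities = p,
                          modularity = NA_real_, method = method),
                     class = "community_solution"))
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  wts <- igraph::E(g)$weight

  if (method == "walktrap") {
    memb <- igraph::membership(igraph::cluster_walktrap(g, weights = wts))
    memb <- .relabel_first_appearance(as.integer(memb))
    q <- igraph::modularity(g, memb, weights = wts)
  } else {
    best_memb <- NULL; best_q <- -Inf
    for (r in seq_len(n_restarts)) {
      set.seed(seed + r - 1L)
      cl <- igraph::cluster_louvain(g, weights = wts, resolution = resolution)
      m <- .relabel_first_appearance(as.integer(igraph::membership(cl)))
      q <- igraph::modularity(g, m, weights = wts)
      if (q > best_q + 1e-12 ||
          (abs(q - best_q) <= 1e-12 && .lex_less(m, best_memb))) {
        best_q <- q; best_memb <- m
      }
    }
    memb <- best_memb; q <- best_q
  }
  memb <- stats::setNames(memb, nm)
  structure(list(membership = memb, n_communities = max(memb),
                 modularity = q, method = method),
            class = "community_solution")
}

.relabel_first_appearance <- function(m) {
  as.integer(factor(m, levels = unique(m)))
}

.lex_less <- function(a, b) {
  if (is.null(b)) return(TRUE)
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

#' @export
print.community_solution <- function(x, ...) {
  cat("Community solution (", x$method, "): ", x$n_communities,
      " communities, modularity Q = ", signif(x$modularity, 4), "\n", sep = "")
  print(split(names(x$membership), x$membership))
  invisible(x)
}

#' Exploratory graph analysis of an item battery
#'
#' Convenience wrapper: fit the EBIC-selected graphical-lasso network and
#' detect communities on it.
#'
#' @inheritParams fit_glasso_network
#' @inheritParams detect_communities
#' @param ... passed to [fit_glasso_network()].
#' @return List of class `ega` with `graph` (`item_graph`) and `communities`
#'   (`community_solution`).
#' @export
ega <- function(data, gamma_ebic = 0.5, method = "louvain", seed = 1L, ...) {
  graph <- fit_glasso_network(data, gamma_ebic = gamma_ebic, ...)
  comm <- detect_communities(graph, method = method, seed = seed)
  structure(list(graph = graph, communities = comm), class = "ega")
}

#' @export
print.ega <- function(x, ...) {
  print(x$graph)
  print(x$communities)
  invisible(x)
}

#' Parametric-bootstrap exploratory graph analysis
#'
#' Fits EGA to the data, then draws `n_boot` replicate datasets from a
#' multivariate normal with the sample correlation matrix (or the
#' model-implied correlation from the selected precision matrix), refits
#' EGA on each, and summarizes the sampling distribution: the median network
#' (elementwise median of replicate partial-correlation matrices), the
#' typical community structure detected on the median network, per-replicate
#' dimension counts, and item stability -- the proportion of replicates that
#' place each item in each typical dimension, after matching replicate
#' communities to typical communities by maximal Jaccard item overlap
#' (ties broken toward the smallest typical index).
#'
#' @param data n x p item matrix.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param gamma_ebic EBIC hyperparameter.
#' @param method community detection method.
#' @param corr_source "sample" to generate replicates from the sample
#'   correlation (default) or "model" for the correlation implied by the
#'   selected sparse precision matrix.
#' @param max_retry redraw cap for replicates whose network fit fails.
#' @param ... passed to [fit_glasso_network()].
#' @return Object of class `boot_ega`: list with `empirical` (`ega` on the
#'   observed data), `W_med`, `typical` (`community_solution`),
#'   `item_stability` (p x K matrix), `dim_counts` (table of replicate
#'   dimension counts), `n_boot`.
#' @export
boot_ega <- function(data, n_boot = 1000L, seed = 1L, gamma_ebic = 0.5,
                     method = "louvain", corr_source = c("sample", "model"),
                     max_retry = 10L, ...) {
  corr_source <- match.arg(corr_source)
  data <- as.matrix(data)
  n <- nrow(data); p <- ncol(data)
  n_boot <- .check_count(n_boot, "n_boot")
  emp <- ega(data, gamma_ebic = gamma_ebic, method = method, seed = seed, ...)
  R <- if (corr_source == "sample") cor(data) else {
    stats::cov2cor(solve(emp$graph$Theta))
  }

  set.seed(seed)
  Ws <- array(NA_real_, c(p, p, n_boot))
  membs <- matrix(NA_integer_, n_boot, p)
  b <- 1L
  failures <- 0L
  while (b <= n_boot) {
    rep_data <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = R)
    fit <- tryCatch(
      ega(rep_data, gamma_ebic = gamma_ebic, method = method,
          seed = seed + b, ...),
      error = function(e) NULL)
    if (is.null(fit)) {
      failures <- failures + 1L
      if (failures > max_retry * n_boot) {
        stop("too many failed bootstrap replicates", call. = FALSE)
      }
      message("bootstrap replicate failed; redrawing")
      next
    }
    Ws[, , b] <- fit$graph$W
    membs[b, ] <- fit$communities$membership
    b <- b + 1L
  }

  W_med <- apply(Ws, c(1, 2), median)
  dimnames(W_med) <- dimnames(emp$graph$W)
  typical <- detect_communities(W_med, method = method, seed = seed)
  K <- typical$n_communities

  S <- matrix(0, p, K, dimnames = list(names(typical$membership),
                                       paste0("dim", seq_len(K))))
  typ_sets <- split(seq_len(p), typical$membership)
  for (bb in seq_len(n_boot)) {
    rep_sets <- split(seq_len(p), membs[bb, ])
    for (rs in rep_sets) {
      jac <- vapply(typ_sets, function(ts) {
        length(intersect(rs, ts)) / length(union(rs, ts))
      }, numeric(1))
      if (max(jac) > 0) {
        k <- which.max(jac)          # ties: smallest index wins
        S[rs, k] <- S[rs, k] + 1
      }
    }
  }
  S <- S / n_boot

  structure(list(empirical = emp, W_med = W_med, typical = typical,
                 item_stability = S,
                 dim_counts = table(apply(membs, 1, max)),
                 n_boot = n_boot),
            class = "boot_ega")
}

#' @export
print.boot_ega <- function(x, ...) {
  cat("Bootstrap EGA (", x$n_boot, " replicates)\n", sep = "")
  cat("Typical structure: ", x$typical$n_communities, " communities\n", sep = "")
  cat("Replicate dimension counts:\n")
  print(x$dim_counts)
  cat("Item stability in own typical dimension:\n")
  own <- x$item_stability[cbind(seq_len(nrow(x$item_stability)),
                                x$typical$membership)]
  print(round(stats::setNames(own, rownames(x$item_stability)), 3))
  invisible(x)
}

#' Standardized network community scores
#'
#' Each item's network loading on its community is the sum of the absolute
#' partial-correlation weights connecting it to the other items of that
#' community; within each community the loadings are scaled to sum to one,
#' and the community score is the weighted sum of the standardized items,
#' itself standardized to mean 0 / SD 1.
#'
#' @param data n x p item matrix (rows aligned with the scores wanted).
#' @param W p x p partial-correlation network (e.g. the median bootstrap
#'   network).
#' @param communities a `community_solution` over the same items.
#' @return Object of class `network_scores`: list with `scores` (n x K
#'   standardized matrix) and `weights` (p x K item-weight matrix).
#' @export
network_scores <- function(data, W, communities) {
  data <- as.matrix(data)
  memb <- communities$membership
  p <- length(memb)
  stopifnot(ncol(data) == p, ncol(W) == p)
  K <- communities$n_communities
  A <- abs(W)
  diag(A) <- 0
  weights <- matrix(0, p, K,
                    dimnames = list(names(memb), paste0("dim", seq_len(K))))
  Z <- scale(data)
  scores <- matrix(0, nrow(data), K,
                   dimnames = list(NULL, paste0("dim", seq_len(K))))
  for (k in seq_len(K)) {
    idx <- which(memb == k)
    if (!length(idx)) stop("empty community ", k, call. = FALSE)
    if (length(idx) == 1L) {
      weights[idx, k] <- 1
    } else {
      load <- rowSums(A[idx, idx, drop = FALSE])
      if (sum(load) == 0) load <- rep(1, length(idx))  # isolated community
      weights[idx, k] <- load / sum(load)
    }
    scores[, k] <- Z[, idx, drop = FALSE] %*% weights[idx, k]
    scores[, k] <- .zscore(scores[, k])
  }
  structure(list(scores = scores, weights = weights),
            class = "network_scores")
}

#' Eigenvalue-greater-than-one heuristic for the number of communities
#'
#' Counts the eigenvalues of the item correlation matrix that exceed 1
#' (strictly) -- a rough estimate of the number of distinct communities.
#'
#' @param x an n x p data matrix, or a p x p correlation matrix (detected as
#'   a square symmetric matrix with unit diagonal).
#' @return Integer count.
#' @export
eigenvalue_heuristic <- function(x) {
  x <- as.matrix(x)
  is_corr <- nrow(x) == ncol(x) && max(abs(x - t(x))) < 1e-10 &&
    all(abs(diag(x) - 1) < 1e-10)
  R <- if (is_corr) x else cor(x)
  if (ncol(R) < 2L) stop("need at least 2 items", call. = FALSE)
  sum(eigen(R, symmetric = TRUE, only.values = TRUE)$values > 1)
}

#' Marginal Pearson correlation report over items, scores, and age variables
#'
#' Aggregates the session-level data to one record per subject by averaging
#' over sessions, then computes the full Pearson correlation matrix over the
#' 15 items, the K network scores, age acceleration, and chronological age
#' -- the descriptive "positive manifold" view of the battery.
#'
#' @param phenotypes long-format phenotype table (needs `subject_id`,
#'   the item columns, `accel`, `age`).
#' @param scores matrix of network scores aligned with the rows of
#'   `phenotypes` (e.g. from [network_scores()]), or NULL to omit.
#' @return Correlation matrix (items, scores, accel, age).
#' @export
marginal_correlation_report <- function(phenotypes, scores = NULL) {
  items <- intersect(unlist(battery_items()), colnames(phenotypes))
  block <- phenotypes[, c(items, "accel", "age"), drop = FALSE]
  if (!is.null(scores)) {
    sc <- if (inherits(scores, "network_scores")) scores$scores else as.matrix(scores)
    block <- cbind(block[, items, drop = FALSE], sc,
                   block[, c("accel", "age"), drop = FALSE])
  }
  agg <- aggregate(block, by = list(subject_id = phenotypes$subject_id), FUN = mean)
  cor(as.matrix(agg[, -1L]))
}
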
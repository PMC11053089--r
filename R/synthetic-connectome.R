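#' Signal configuration for synthetic connectomes
#'
#' Controls where and how strongly phenotype-related signal is planted in
#' the generated Fisher-z connectivity matrices. Signal lives on a fraction
#' of the edges among a designated set of nodes (labelled "Limbic" in the
#' synthetic node metadata); the default density (all 190 edges among the
#' 20 signal nodes, split between the mapped phenotypes) is calibrated so
#' that ridge prediction of the phenotype from the full edge set reproduces
#' the accuracy scale reported for real connectomes (median Spearman rho
#' about 0.3-0.6) against the random Gram of the ~35,000 baseline edges.
#' Each signal edge is constructed as
#' `baseline_z_mean + baseline_z_sd * (sign * rho * z(phenotype) +
#' sqrt(1 - rho^2) * noise)` with `rho = signal_strength`, so its population
#' correlation with the phenotype is exactly `sign * rho` and its marginal
#' scale matches the non-signal edges. Non-signal edges are pure baseline
#' noise, Normal(`baseline_z_mean`, `baseline_z_sd`) -- a typical
#' resting-state Fisher-z range.
#'
#' @param signal_nodes node ids that host the signal edges.
#' @param signal_edge_fraction fraction of within-signal-node edges that
#'   carry effect.
#' @param signal_strength population correlation between each signal edge
#'   and its phenotype, in (-1, 1).
#' @param baseline_z_mean,baseline_z_sd mean and SD of baseline edges
#'   (Fisher-z units).
#' @param phenotype_map named numeric vector of +/- 1: which phenotype
#'   columns load on the signal edges and with which sign. Signal edges are
#'   split round-robin across the mapped phenotypes.
#' @return A list of class `connectome_signal_config`.
#' @export
connectome_signal_config <- function(signal_nodes = 1:20,
                                     signal_edge_fraction = 1,
                                     signal_strength = 0.5,
                                     baseline_z_mean = 0.2,
                                     baseline_z_sd = 0.2,
                                     phenotype_map = c(accel = 1, memory = -1)) {
  if (abs(signal_strength) >= 1) {
    stop("invalid config: signal_strength must lie in (-1, 1)", call. = FALSE)
  }
  if (is.null(names(phenotype_map)) || any(names(phenotype_map) == "")) {
    stop("invalid config: phenotype_map must be a named vector", call. = FALSE)
  }
  structure(list(
    signal_nodes = as.integer(signal_nodes),
    signal_edge_fraction = .check_fraction(signal_edge_fraction,
                                           "signal_edge_fraction"),
    signal_strength = as.numeric(signal_strength),
    baseline_z_mean = as.numeric(baseline_z_mean),
    baseline_z_sd = .check_positive(baseline_z_sd, "baseline_z_sd"),
    phenotype_map = sign(phenotype_map)
  ), class = "connectome_signal_config")
}

#' Generate synthetic Fisher-z connectomes with planted phenotype signal
#'
#' One symmetric `n_nodes x n_nodes` matrix (zero diagonal) per row of
#' `phenotypes`. Edges are generated in the canonical edge-vector order and
#' folded back into matrices, so the edge-vector form and the matrix form
#' agree by construction.
#'
#' @param phenotypes `data.frame` with one row per imaged subject, holding
#'   at least the columns named in `sig$phenotype_map` (standardized
#'   internally).
#' @param sig a [connectome_signal_config()].
#' @param seed integer seed.
#' @param n_nodes number of nodes (default 268).
#' @return A list of class `connectome_set` with elements `edges` (subjects
#'   x edges matrix in canonical order), `matrices` (list of symmetric
#'   matrices), `signal_edges` (`data.frame` of edge index, phenotype,
#'   sign), and `n_nodes`.
#' @export
generate_connectomes <- function(phenotypes, sig = connectome_signal_config(),
                                 seed, n_nodes = 268L) {
  stopifnot(inherits(sig, "connectome_signal_config"), is.data.frame(phenotypes))
  n_nodes <- .check_count(n_nodes, "n_nodes", min = 2L)
  if (length(sig$signal_nodes) &&
      (min(sig$signal_nodes) < 1 || max(sig$signal_nodes) > n_nodes)) {
    stop("invalid config: signal_nodes outside 1..n_nodes", call. = FALSE)
  }
  phen_names <- names(sig$phenotype_map)
  missing_ph <- setdiff(phen_names, colnames(phenotypes))
  if (length(missing_ph)) {
    stop("phenotypes table lacks columns: ", paste(missing_ph, collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  n <- nrow(phenotypes)
  n_edges <- n_nodes * (n_nodes - 1L) / 2L

  edges <- matrix(rnorm(n * n_edges, sig$baseline_z_mean, sig$baseline_z_sd),
                  n, n_edges)

  # canonical indices of edges with both endpoints in the signal-node set
  pairs <- edge_index_table(n_nodes)
  candidate <- which(pairs$i %in% sig$signal_nodes &
                     pairs$j %in% sig$signal_nodes)
  n_sig <- round(length(candidate) * sig$signal_edge_fraction)
  chosen <- if (n_sig > 0) sort(sample(candidate, n_sig)) else integer(0)

  signal_edges <- data.frame(edge = integer(0), phenotype = character(0),
                             sign = numeric(0))
  if (length(chosen) && abs(sig$signal_strength) > 0) {
    assign_ph <- rep_len(seq_along(phen_names), length(chosen))
    rho <- abs(sig$signal_strength)
    base_sign <- sign(sig$signal_strength)
    for (k in seq_along(chosen)) {
      e <- chosen[k]
      ph <- phen_names[assign_ph[k]]
      s <- base_sign * sig$phenotype_map[[ph]]
      z_ph <- .zscore(phenotypes[[ph]])
      edges[, e] <- sig$baseline_z_mean + sig$baseline_z_sd *
        (s * rho * z_ph + sqrt(1 - rho^2) * rnorm(n))
      signal_edges <- rbind(signal_edges,
                            data.frame(edge = e, phenotype = ph, sign = s))
    }
  }

  mats <- lapply(seq_len(n), function(i) {
    devectorize_connectivity(edges[i, ], n_nodes)
  })
  if (!is.null(phenotypes$subject_id)) names(mats) <- phenotypes$subject_id

  structure(list(edges = edges, matrices = mats,
                 signal_edges = signal_edges, n_nodes = n_nodes),
            class = "connectome_set")
}
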
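#' Eigenvector centrality of a nonnegative symmetric network
#'
#' Principal eigenvector by power iteration (tolerance 1e-10), nonnegative
#' by Perron-Frobenius and normalized to unit Euclidean norm -- the
#' convention under which 268-node coefficient networks yield centralities
#' in the 0.1--0.2 range for their hub nodes. On a disconnected network the
#' eigenvector concentrates on the dominant component (warning).
#'
#' @param W nonnegative symmetric matrix with at least one nonzero entry.
#' @param tol convergence tolerance.
#' @param max_iter iteration cap.
#' @return Numeric vector of centralities (unit Euclidean norm).
#' @export
eigenvector_centrality <- function(W, tol = 1e-10, max_iter = 10000L) {
  W <- as.matrix(W)
  if (any(W < 0)) stop("W must be nonnegative", call. = FALSE)
  if (max(abs(W - t(W))) > 1e-8) stop("W must be symmetric", call. = FALSE)
  if (all(W == 0)) stop("W has no nonzero entry", call. = FALSE)
  n <- ncol(W)
  deg <- rowSums(W)
  if (any(deg == 0)) {
    warning("disconnected nodes: eigenvector concentrates on the ",
            "dominant component")
  }
  # power-iterate on W + rI: same Perron eigenvector, but the shift makes
  # the dominant eigenvalue strictly largest in magnitude (bipartite
  # networks otherwise oscillate between +/- lambda_max)
  shift <- max(deg)
  Ws <- W + diag(shift, n)
  v <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    v_new <- Ws %*% v
    nrm <- sqrt(sum(v_new^2))
    if (nrm == 0) stop("power iteration collapsed to zero", call. = FALSE)
    v_new <- as.numeric(v_new) / nrm
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      break
    }
    v <- v_new
  }
  v <- abs(v)   # Perron vector sign convention
  v / sqrt(sum(v^2))
}

#' Top fraction of edges of a nonnegative coefficient network
#'
#' Keeps the `ceiling(fraction * n_edges)` largest-weight edges (2% in the
#' published network visualizations), ties broken by the canonical edge
#' index (smaller index wins); zero-weight edges are dropped.
#'
#' @param W nonnegative symmetric matrix (one signed part of a coefficient
#'   network).
#' @param fraction fraction of all edges to keep, in (0, 1].
#' @return Object of class `thresholded_network`: `data.frame` with columns
#'   `i`, `j`, `weight`, plus attributes `n_nodes` and `fraction`.
#' @export
top_fraction_edges <- function(W, fraction = 0.02) {
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  W <- as.matrix(W)
  n <- ncol(W)
  v <- vectorize_connectivity(W)
  if (all(v == 0)) {
    warning("all-zero matrix: empty thresholded network")
    out <- data.frame(i = integer(0), j = integer(0), weight = numeric(0))
  } else {
    k <- ceiling(fraction * length(v))
    ord <- order(-v, seq_along(v))      # weight desc, then canonical index
    keep <- ord[seq_len(k)]
    keep <- keep[v[keep] > 0]
    tab <- edge_index_table(n)
    out <- data.frame(i = tab$i[keep], j = tab$j[keep], weight = v[keep])
  }
  attr(out, "n_nodes") <- n
  attr(out, "fraction") <- fraction
  class(out) <- c("thresholded_network", "data.frame")
  out
}

#' Lobe-pair summary of high- and low-phenotype networks
#'
#' The numeric backbone of a Hinton-style diagram: for each unordered pair
#' of lobes, `size` is the number of edges present in the high-phenotype
#' plus low-phenotype thresholded networks divided by the number of
#' possible edges between the two lobes (`n_a * n_b` for distinct lobes,
#' `n_a * (n_a - 1) / 2` within a lobe), and `color` is the signed
#' difference (high minus low) of those edge counts.
#'
#' @param high_net,low_net `thresholded_network` objects (e.g. the
#'   positive- and negative-weight models of one phenotype).
#' @param node_metadata `data.frame` with `node_id` and `lobe` for every
#'   node.
#' @return List of class `lobe_summary` with `size` and `color` (symmetric
#'   lobe x lobe matrices) and `lobes`.
#' @export
lobe_summary <- function(high_net, low_net, node_metadata) {
  n_nodes <- attr(high_net, "n_nodes")
  if (is.null(n_nodes)) n_nodes <- max(node_metadata$node_id)
  if (nrow(node_metadata) < n_nodes || anyNA(node_metadata$lobe)) {
    stop("every node needs a lobe label", call. = FALSE)
  }
  lobe_of <- node_metadata$lobe[order(node_metadata$node_id)]
  lobes <- sort(unique(lobe_of))
  L <- length(lobes)
  counts <- table(factor(lobe_of, levels = lobes))

  pair_counts <- function(net) {
    m <- matrix(0, L, L, dimnames = list(lobes, lobes))
    if (nrow(net)) {
      la <- factor(lobe_of[net$i], levels = lobes)
      lb <- factor(lobe_of[net$j], levels = lobes)
      for (e in seq_len(nrow(net))) {
        m[la[e], lb[e]] <- m[la[e], lb[e]] + 1
        if (la[e] != lb[e]) m[lb[e], la[e]] <- m[lb[e], la[e]] + 1
      }
    }
    m
  }
  hi <- pair_counts(high_net)
  lo <- pair_counts(low_net)
  possible <- outer(as.numeric(counts), as.numeric(counts))
  diag(possible) <- as.numeric(counts) * (as.numeric(counts) - 1) / 2
  possible[possible == 0] <- NA_real_
  size <- (hi + lo) / possible
  color <- hi - lo
  dimnames(size) <- dimnames(color) <- list(lobes, lobes)
  structure(list(size = size, color = color, lobes = lobes),
            class = "lobe_summary")
}

#' Ranked region-importance tables per phenotype and network sign
#'
#' For each phenotype's averaged signed coefficient matrices, computes
#' eigenvector centrality per sign and reports the top-k nodes with their
#' coordinates and lobes (centralities rounded to 2 decimals in the printed
#' table layout), plus the pairwise overlap of top-k node sets across
#' phenotypes.
#'
#' @param coef_list named list (one element per phenotype) of lists with
#'   nonnegative symmetric matrices `positive` and `negative`, as returned
#'   by [collect_coefficients()] (an `rcpm` object is also accepted).
#' @param node_metadata node metadata table (`node_id`, `x`, `y`, `z`,
#'   `lobe`).
#' @param k_top rows per table (default 6; truncated with a warning if it
#'   exceeds the node count).
#' @return Object of class `importance_report`: `tables` (per phenotype x
#'   sign `data.frame`s), `centrality` (per phenotype x sign vectors),
#'   `overlap` (`data.frame` of pairwise top-k overlaps).
#' @export
importance_report <- function(coef_list, node_metadata, k_top = 6L) {
  coef_list <- lapply(coef_list, function(x) {
    if (inherits(x, "rcpm")) x$coefficients else x
  })
  if (is.null(names(coef_list))) {
    names(coef_list) <- paste0("phenotype", seq_along(coef_list))
  }
  n_nodes <- nrow(node_metadata)
  if (k_top > n_nodes) {
    warning("k_top exceeds node count; truncating to ", n_nodes)
    k_top <- n_nodes
  }
  meta <- node_metadata[order(node_metadata$node_id), ]
  tables <- list()
  centr <- list()
  top_sets <- list()
  for (ph in names(coef_list)) {
    for (sgn in c("positive", "negative")) {
      W <- coef_list[[ph]][[sgn]]
      key <- paste(ph, sgn, sep = ".")
      if (all(W == 0)) {
        centr[[key]] <- rep(0, n_nodes)
      } else {
        centr[[key]] <- eigenvector_centrality(W)
      }
      ord <- order(-centr[[key]], meta$node_id)[seq_len(k_top)]
      tables[[key]] <- data.frame(
        node = meta$node_id[ord], x = meta$x[ord], y = meta$y[ord],
        z = meta$z[ord], lobe = meta$lobe[ord],
        centrality = round(centr[[key]][ord], 2),
        rank = seq_len(k_top))
      top_sets[[key]] <- meta$node_id[ord]
    }
  }
  keys <- names(top_sets)
  overlap <- NULL
  if (length(keys) > 1) {
    cmb <- utils::combn(keys, 2)
    overlap <- data.frame(
      a = cmb[1, ], b = cmb[2, ],
      shared = apply(cmb, 2, function(k2) {
        length(intersect(top_sets[[k2[1]]], top_sets[[k2[2]]]))
      }))
  }
  structure(list(tables = tables, centrality = centr, overlap = overlap,
                 k_top = k_top),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  for (nm in names(x$tables)) {
    cat("--", nm, "--\n")
    print(x$tables[[nm]], row.names = FALSE)
  }
  if (!is.null(x$overlap)) {
    cat("Top-", x$k_top, " node overlap across phenotypes:\n", sep = "")
    print(x$overlap, row.names = FALSE)
  }
  invisible(x)
}
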
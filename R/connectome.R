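#' Canonical edge ordering of a symmetric connectivity matrix
#'
#' Edges are ordered as the row-major lower triangle (0-based i > j):
#' (2,1), (3,1), (3,2), (4,1), ... in 1-based node ids. For a symmetric
#' matrix this equals the column-major upper triangle, which is how the
#' vectorized forms are extracted internally. The ordering is fixed and
#' documented because model coefficient vectors are persisted in it.
#'
#' @param n_nodes number of nodes.
#' @return `data.frame` with columns `edge`, `i`, `j` (`i > j`).
#' @export
edge_index_table <- function(n_nodes) {
  n_nodes <- .check_count(n_nodes, "n_nodes", min = 2L)
  j <- sequence(seq_len(n_nodes - 1L))                 # 1,1,2,1,2,3,...
  i <- rep(2:n_nodes, times = seq_len(n_nodes - 1L))   # 2,3,3,4,4,4,...
  data.frame(edge = seq_along(i), i = i, j = j)
}

#' Vectorize a symmetric connectivity matrix to its edge vector
#'
#' Extracts the unique off-diagonal entries in the canonical edge order,
#' discarding the constant diagonal. A 268-node matrix yields 35,778 edges.
#'
#' @param M symmetric numeric matrix.
#' @return Numeric edge vector of length `n * (n - 1) / 2`.
#' @seealso [devectorize_connectivity()]
#' @export
vectorize_connectivity <- function(M) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    stop("M must be a square matrix", call. = FALSE)
  }
  if (max(abs(M - t(M))) > 1e-8) {
    stop("M must be symmetric", call. = FALSE)
  }
  M[upper.tri(M)]
}

#' Rebuild a symmetric connectivity matrix from an edge vector
#'
#' Inverse of [vectorize_connectivity()]; the diagonal is stored as zero.
#'
#' @param v edge vector in canonical order.
#' @param n_nodes number of nodes; the vector length must equal
#'   `n_nodes * (n_nodes - 1) / 2`.
#' @return Symmetric `n_nodes x n_nodes` matrix with zero diagonal.
#' @export
devectorize_connectivity <- function(v, n_nodes) {
  n_nodes <- .check_count(n_nodes, "n_nodes", min = 2L)
  if (length(v) != n_nodes * (n_nodes - 1L) / 2L) {
    stop("edge vector length ", length(v), " is not the triangular number ",
         "for ", n_nodes, " nodes", call. = FALSE)
  }
  M <- matrix(0, n_nodes, n_nodes)
  M[upper.tri(M)] <- v
  M + t(M)
}

#' Concatenate resting-state runs along the time dimension
#'
#' Connectivity is computed on the concatenated series (two runs in the
#' emulated study), which improves reliability of the estimates.
#'
#' @param runs list of frames-x-nodes matrices with equal node counts.
#' @return Single row-stacked matrix.
#' @export
concat_runs <- function(runs) {
  stopifnot(is.list(runs), length(runs) >= 1L)
  ncols <- vapply(runs, ncol, integer(1))
  if (length(unique(ncols)) != 1L) {
    stop("runs have mismatched node counts: ",
         paste(unique(ncols), collapse = ", "), call. = FALSE)
  }
  do.call(rbind, runs)
}

# discrete-cosine high-pass basis: DCT components with frequency below the
# cutoff (periods longer than 1/cutoff seconds), excluding the constant term
.dct_basis <- function(n_frames, tr, highpass_hz) {
  if (highpass_hz <= 0) return(NULL)
  t_idx <- seq_len(n_frames) - 0.5
  k_max <- floor(2 * n_frames * tr * highpass_hz)
  if (k_max < 1) return(NULL)
  sapply(seq_len(k_max), function(k) cos(pi * k * t_idx / n_frames))
}

#' Regress confounds and slow drifts out of node time series
#'
#' Removes from every node column its least-squares projection onto the
#' column space of an intercept, the supplied confound columns, and a
#' discrete-cosine high-pass basis containing all cosine components slower
#' than `highpass_hz` (default 0.008 Hz). High-pass filtering is implemented
#' as regression on the cosine basis -- the confound-regression framing --
#' rather than a causal filter.
#'
#' @param ts frames-x-nodes matrix of node time series.
#' @param confounds optional frames-x-k matrix of confound regressors,
#'   aligned with the frames of `ts`.
#' @param highpass_hz high-pass cutoff in Hz; 0 disables the cosine basis.
#' @param tr sampling interval in seconds (default 0.8).
#' @return Matrix of residual time series, same shape as `ts`.
#' @export
clean_timeseries <- function(ts, confounds = NULL, highpass_hz = 0.008,
                             tr = 0.8) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stop("need at least 3 frames", call. = FALSE)
  if (!is.null(confounds) && nrow(as.matrix(confounds)) != nrow(ts)) {
    stop("confound rows do not align with frames", call. = FALSE)
  }
  X <- cbind(intercept = rep(1, nrow(ts)), confounds,
             .dct_basis(nrow(ts), tr, highpass_hz))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("rank-deficient confound matrix; using pseudoinverse projection")
    P <- MASS::ginv(X)
    return(ts - X %*% (P %*% ts))
  }
  ts - X %*% qr.coef(qx, ts)
}

#' Fisher-z connectivity matrix from node time series
#'
#' Entry (i, j) is `atanh(r_ij)` for the Pearson correlation of node columns
#' i and j, with `|r|` clipped at `clip_r` before the transform so perfectly
#' correlated pairs stay finite. Constant columns yield zero edges with a
#' warning. The diagonal is stored as zero.
#'
#' @param ts frames-x-nodes matrix (>= 3 frames).
#' @param clip_r clip for `|r|` (default `1 - 1e-7`).
#' @return Symmetric Fisher-z matrix with zero diagonal.
#' @export
compute_connectivity <- function(ts, clip_r = 1 - 1e-7) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stop("need at least 3 frames", call. = FALSE)
  const <- apply(ts, 2, function(x) sd(x) == 0 || !is.finite(sd(x)))
  r <- suppressWarnings(cor(ts))
  if (any(const)) {
    warning(sum(const), " constant node column(s); their edges set to 0")
    r[const, ] <- 0
    r[, const] <- 0
  }
  r[is.na(r)] <- 0
  r <- pmin(pmax(r, -clip_r), clip_r)
  z <- atanh(r)
  z <- (z + t(z)) / 2   # enforce exact symmetry against rounding
  diag(z) <- 0
  z
}
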
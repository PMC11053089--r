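#' Build the model-ready design for the hierarchical robust regression
#'
#' Assembles the response matrix (the four network community scores) and the
#' fixed-effect design used by the multivariate model: age acceleration,
#' chronological age, and the time-difference covariate standardized;
#' session as the raw session number (1..3) so its coefficient is a
#' per-session practice effect; sex as a female indicator; and the seven
#' cell-count covariates standardized. Responses are standardized, so all
#' coefficients are on the standardized scale of the published effect table.
#'
#' @param phenotypes long-format phenotype table (one row per subject x
#'   session) with `subject_id`, `session`, `accel`, `age`, `time_diff`,
#'   `sex`, and the seven cell-count columns.
#' @param scores `network_scores` object or numeric matrix of responses
#'   aligned with the rows of `phenotypes`.
#' @return List of class `bhm_design`: `Y` (n x R standardized responses),
#'   `X` (n x 13 design with intercept), `subject` (integer index),
#'   `session` (numeric), `terms` (predictor names), `response_names`.
#' @export
build_design <- function(phenotypes, scores) {
  sc <- if (inherits(scores, "network_scores")) scores$scores else as.matrix(scores)
  if (nrow(sc) != nrow(phenotypes)) {
    stop("scores and phenotypes are not aligned: ", nrow(sc), " vs ",
         nrow(phenotypes), " rows", call. = FALSE)
  }
  need <- c("subject_id", "session", "accel", "age", "time_diff", "sex",
            cell_count_names())
  missing_cols <- setdiff(need, colnames(phenotypes))
  if (length(missing_cols)) {
    stop("phenotypes table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!stats::complete.cases(phenotypes[, need]) |
                 !stats::complete.cases(sc))
  if (length(bad)) {
    stop("missing cells in rows: ", paste(utils::head(bad, 10), collapse = ", "),
         call. = FALSE)
  }
  Y <- apply(sc, 2, .zscore)
  X <- cbind(
    "(Intercept)" = 1,
    AgeAccelGrim = .zscore(phenotypes$accel),
    Age = .zscore(phenotypes$age),
    TimeDiff = .zscore(phenotypes$time_diff),
    Session = as.numeric(phenotypes$session),
    SexFemale = as.numeric(phenotypes$sex == "female")
  )
  cells <- apply(as.matrix(phenotypes[, cell_count_names()]), 2, .zscore)
  X <- cbind(X, cells)
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  structure(list(
    Y = Y, X = X,
    subject = as.integer(factor(phenotypes$subject_id,
                                levels = unique(phenotypes$subject_id))),
    session = as.numeric(phenotypes$session),
    terms = colnames(X),
    response_names = colnames(Y)
  ), class = "bhm_design")
}
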
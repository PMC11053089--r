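#' Cohort configuration for the synthetic study generator
#'
#' Defaults reproduce the published cohort descriptors of the study the
#' pipeline emulates: 103 participants (98 with fMRI), three cognitive
#' testing sessions, age 68.98 +/- 5.68 years truncated to 59--81, an
#' age-acceleration variable with SD 3.49 years orthogonal to age, 73/103
#' female, and a 268-node whole-brain parcellation.
#'
#' @param n_subjects number of participants.
#' @param n_fmri number of participants with connectomes (`<= n_subjects`);
#'   by convention the first `n_fmri` subject ids.
#' @param n_sessions cognitive testing sessions per participant.
#' @param age_mean,age_sd,age_range mean, SD (years) and truncation range of
#'   the chronological-age distribution.
#' @param accel_sd SD (years) of the age-acceleration variable.
#' @param prop_female expected fraction of female participants.
#' @param n_nodes nodes in the connectivity parcellation.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 103L, n_fmri = 98L, n_sessions = 3L,
                          age_mean = 68.98, age_sd = 5.68,
                          age_range = c(59, 81), accel_sd = 3.49,
                          prop_female = 73 / 103, n_nodes = 268L) {
  cfg <- list(
    n_subjects = .check_count(n_subjects, "n_subjects"),
    n_fmri = .check_count(n_fmri, "n_fmri", min = 0L),
    n_sessions = .check_count(n_sessions, "n_sessions"),
    age_mean = as.numeric(age_mean),
    age_sd = .check_positive(age_sd, "age_sd"),
    age_range = as.numeric(age_range),
    accel_sd = .check_positive(accel_sd, "accel_sd"),
    prop_female = .check_fraction(prop_female, "prop_female"),
    n_nodes = .check_count(n_nodes, "n_nodes", min = 2L)
  )
  if (cfg$n_fmri > cfg$n_subjects) {
    stop("invalid config: n_fmri must not exceed n_subjects", call. = FALSE)
  }
  if (length(cfg$age_range) != 2L || diff(cfg$age_range) <= 0) {
    stop("invalid config: age_range must be an increasing pair", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

#' Names of the blood-cell-count adjustment covariates
#' @return Character vector of the seven cell-count column names.
#' @export
cell_count_names <- function() {
  c("NK", "Mono", "Gran", "PlasmaBlast", "CD8pCD28nCD45RAn",
    "CD8.naive", "CD4.naive")
}

#' Names of the 15 cognitive battery items, grouped by latent domain
#'
#' Three items per domain: processing speed, memory, spatial visualization,
#' reasoning, vocabulary. In the generator and downstream analysis, spatial
#' visualization and reasoning load on one shared latent factor (the
#' empirically observed four-community structure), so the four generating
#' factors cover processing speed, memory, spatial/reasoning (6 items) and
#' vocabulary.
#' @return Named list mapping the four latent factors to item names.
#' @export
battery_items <- function() {
  list(
    proc_speed = c("DigSym", "PatCom", "LetCom"),
    memory = c("Recall", "LogMem", "PAssoc"),
    spatial_reasoning = c("MatRea", "Ship", "LetSet", "SpaRel", "PapFld", "FrmBrd"),
    vocabulary = c("Vocab", "SynVoc", "AntVoc")
  )
}

#' Generate the subject-level part of a synthetic cohort
#'
#' Ages are drawn truncated-normal inside `age_range` (inverse-CDF method);
#' age acceleration is drawn Normal(0, `accel_sd`) and then residualized
#' against age by exact least squares, so the sample correlation between the
#' two is zero to machine precision -- mirroring the defining property of an
#' age-acceleration residual. Sex is Bernoulli(`prop_female`); the
#' time-difference covariate (days between blood draw/scan and cognitive
#' testing) is log-normal matched to the published mean 133.54 and SD 124.13
#' days; the seven cell-count covariates are i.i.d. standard normal
#' adjustment columns.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return A `data.frame` with one row per subject: `subject_id`, `age`,
#'   `accel`, `sex` ("female"/"male"), `time_diff`, `has_fmri`, and the seven
#'   cell-count columns.
#' @export
generate_cohort <- function(config = cohort_config(), seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n_subjects

  lo <- pnorm(config$age_range[1], config$age_mean, config$age_sd)
  hi <- pnorm(config$age_range[2], config$age_mean, config$age_sd)
  age <- qnorm(runif(n, lo, hi), config$age_mean, config$age_sd)

  accel_raw <- rnorm(n, 0, config$accel_sd)
  accel <- lm.fit(cbind(1, age), accel_raw)$residuals

  sex <- ifelse(rbinom(n, 1L, config$prop_female) == 1L, "female", "male")

  # log-normal moment match: mean 133.54, SD 124.13 days
  m <- 133.54; s <- 124.13
  sig2 <- log(1 + (s / m)^2)
  time_diff <- rlnorm(n, meanlog = log(m) - sig2 / 2, sdlog = sqrt(sig2))

  cells <- matrix(rnorm(n * 7L), n, 7L,
                  dimnames = list(NULL, cell_count_names()))

  out <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = age,
    accel = accel,
    sex = sex,
    time_diff = time_diff,
    has_fmri = seq_len(n) <= config$n_fmri,
    check.names = FALSE
  )
  cbind(out, as.data.frame(cells, check.names = FALSE))
}

#' Generate synthetic node metadata for the parcellation
#'
#' Every node gets an MNI-style coordinate triple and exactly one lobe label
#' from the ten categories used for lobe-level reporting. Nodes listed in
#' `signal_nodes` are labelled "Limbic" so that planted connectome signal
#' sits in limbic/medial-temporal territory, as in the study's region
#' importance tables; all coordinates and remaining labels are synthetic.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param seed integer seed.
#' @param signal_nodes integer node ids forced to the "Limbic" lobe.
#' @return A `data.frame` with columns `node_id`, `x`, `y`, `z`, `lobe`.
#' @export
generate_node_metadata <- function(n_nodes = 268L, seed, signal_nodes = 1:20) {
  n_nodes <- .check_count(n_nodes, "n_nodes", min = 2L)
  if (length(signal_nodes) && (min(signal_nodes) < 1 || max(signal_nodes) > n_nodes)) {
    stop("invalid config: signal_nodes outside 1..n_nodes", call. = FALSE)
  }
  set.seed(seed)
  lobes <- c("Limbic", "Prefrontal", "Temporal", "Motor", "Subcortical",
             "Brainstem", "Cerebellum", "Parietal", "Occipital", "Insula")
  lab <- sample(rep_len(lobes, n_nodes))
  lab[signal_nodes] <- "Limbic"
  data.frame(
    node_id = seq_len(n_nodes),
    x = round(runif(n_nodes, -70, 70), 1),
    y = round(runif(n_nodes, -105, 70), 1),
    z = round(runif(n_nodes, -60, 80), 1),
    lobe = lab
  )
}
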
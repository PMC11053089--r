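# Pipeline orchestration and delimited-text I/O.

#' Read and write phenotype tables, matrices, and node metadata
#'
#' Plain-text round-trip I/O at full numeric precision: phenotype tables as
#' comma-separated values with a header row (one record per subject x
#' session), connectivity matrices as tab-separated numeric grids, node
#' metadata as tab-separated (`node_id`, `x`, `y`, `z`, `lobe`). Malformed
#' files (inconsistent row lengths, non-numeric matrix cells) raise a parse
#' error naming the offending line.
#'
#' @param x object to write.
#' @param path file path.
#' @return The read functions return the parsed object; write functions
#'   return `path` invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_phenotypes <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_phenotypes <- function(path) {
  nf <- count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    stop("parse error in ", path, ": line ", bad,
         " has ", nf[bad], " fields (expected ", nf[1], ")", call. = FALSE)
  }
  read.csv(path, check.names = FALSE)
}

#' @rdname pipeline_io
#' @export
write_matrix <- function(x, path) {
  write.table(x, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_matrix <- function(path) {
  nf <- count.fields(path, sep = "\t")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    stop("parse error in ", path, ": line ", bad,
         " has ", nf[bad], " fields (expected ", nf[1], ")", call. = FALSE)
  }
  m <- as.matrix(read.delim(path, header = FALSE, colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

#' @rdname pipeline_io
#' @export
write_node_metadata <- function(x, path) {
  write.table(x, path, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_node_metadata <- function(path) {
  out <- read.delim(path)
  need <- c("node_id", "x", "y", "z", "lobe")
  missing_cols <- setdiff(need, colnames(out))
  if (length(missing_cols)) {
    stop("parse error in ", path, ": missing columns ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out
}

#' Pipeline configuration
#'
#' Nested stage configurations for the end-to-end synthetic-study driver.
#' Stage seeds are derived deterministically from the global seed via
#' [stage_seed()], so any stage can be reproduced in isolation.
#'
#' @param seed global seed.
#' @param cohort a [cohort_config()].
#' @param effects an [effect_config()].
#' @param signal a [connectome_signal_config()].
#' @param n_boot bootstrap replicates for the EGA stage.
#' @param sampler a [sampler_config()] for the model stage (its seed is
#'   overridden by the derived stage seed).
#' @param rcpm an [rcpm_config()] (seed likewise derived).
#' @param rcpm_phenotypes phenotypes to run through the connectome stage;
#'   any of "accel", "age", or a network-score column.
#' @param control_adjusted also run the control-adjusted confound variants.
#' @param permutation run permutation tests in the connectome stage.
#' @param stages character vector of stages to execute, in order, from
#'   "simulate", "ega", "model", "rcpm", "importance".
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            cohort = cohort_config(),
                            effects = effect_config(),
                            signal = connectome_signal_config(),
                            n_boot = 1000L,
                            sampler = sampler_config(),
                            rcpm = rcpm_config(),
                            rcpm_phenotypes = c("accel", "memory"),
                            control_adjusted = TRUE,
                            permutation = FALSE,
                            stages = c("simulate", "ega", "model", "rcpm",
                                       "importance")) {
  structure(list(seed = as.integer(seed), cohort = cohort, effects = effects,
                 signal = signal, n_boot = .check_count(n_boot, "n_boot"),
                 sampler = sampler, rcpm = rcpm,
                 rcpm_phenotypes = rcpm_phenotypes,
                 control_adjusted = isTRUE(control_adjusted),
                 permutation = isTRUE(permutation),
                 stages = match.arg(stages, several.ok = TRUE)),
            class = "pipeline_config")
}

#' Run the full synthetic-study analysis pipeline
#'
#' Executes simulate -> ega -> model -> rcpm -> importance on a generated
#' cohort, mirroring the analysis flow of the emulated study: cognitive
#' scores for all subjects feed the exploratory graph analysis and the
#' hierarchical model at the session level, while the connectome stage uses
#' one session-mean phenotype value per imaged subject (subjects without
#' connectomes are retained upstream and dropped, with a message, for the
#' connectome stage). The age-acceleration and age analyses control for
#' each other plus sex and time difference; their control-adjusted variants
#' additionally control for the four cognitive scores. Cognitive-phenotype
#' analyses control for sex and time difference, with age and
#' age-acceleration added in the control-adjusted variants.
#'
#' @param config a [pipeline_config()].
#' @return List of class `pipeline_result` with per-stage outputs and a
#'   `manifest` (`data.frame` of stage, seed, checksum, status).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list()
  manifest <- data.frame(stage = character(0), seed = integer(0),
                         checksum = character(0), status = character(0))
  note <- function(stage, seed, obj) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, seed = seed,
      checksum = digest::digest(obj, algo = "md5"),
      status = "complete"))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  items <- unlist(battery_items())

  # --- simulate
  sseed <- stage_seed(config$seed, "simulate")
  sim <- run_stage("simulate", {
    cohort <- generate_cohort(config$cohort, seed = sseed)
    phen <- generate_cognitive_battery(cohort, config$effects,
                                       seed = sseed + 1L,
                                       n_sessions = config$cohort$n_sessions)
    meta <- generate_node_metadata(config$cohort$n_nodes, seed = sseed + 2L,
                                   signal_nodes = config$signal$signal_nodes)
    list(cohort = cohort, phenotypes = phen, node_metadata = meta)
  })
  res$simulate <- sim
  note("simulate", sseed, sim)
  if (!"ega" %in% config$stages) return(.pipeline_done(res, manifest))

  # --- ega
  eseed <- stage_seed(config$seed, "ega")
  egar <- run_stage("ega", {
    boot <- boot_ega(as.matrix(sim$phenotypes[, items]),
                     n_boot = config$n_boot, seed = eseed)
    sc <- network_scores(as.matrix(sim$phenotypes[, items]),
                         boot$W_med, boot$typical)
    colnames(sc$scores) <- .label_communities(boot$typical)
    list(boot = boot, scores = sc,
         marginal = marginal_correlation_report(sim$phenotypes, sc),
         eigen_count = eigenvalue_heuristic(
           .session_mean_items(sim$phenotypes, items)))
  })
  res$ega <- egar
  note("ega", eseed, egar$boot$typical$membership)
  if (!"model" %in% config$stages) return(.pipeline_done(res, manifest))

  # --- model
  mseed <- stage_seed(config$seed, "model")
  model <- run_stage("model", {
    des <- build_design(sim$phenotypes, egar$scores)
    smp <- config$sampler
    smp$seed <- mseed
    fit_bhm(des, smp)
  })
  res$model <- model
  note("model", mseed, bhm_draws(model, "^beta\\["))
  if (!"rcpm" %in% config$stages) return(.pipeline_done(res, manifest))

  # --- rcpm (phenotype + control-adjusted variants per analysis)
  rseed <- stage_seed(config$seed, "rcpm")
  rc <- run_stage("rcpm", {
    fmri <- sim$phenotypes$has_fmri[!duplicated(sim$phenotypes$subject_id)]
    if (!all(fmri)) {
      message(sum(!fmri), " subject(s) without connectomes dropped for the ",
              "connectome stage")
    }
    subj <- .subject_table(sim$phenotypes, egar$scores)
    subj_fmri <- subj[fmri, , drop = FALSE]
    conn <- generate_connectomes(subj_fmri, config$signal, seed = rseed,
                                 n_nodes = config$cohort$n_nodes)
    score_names <- colnames(egar$scores$scores)
    runs <- list()
    for (ph in config$rcpm_phenotypes) {
      base_conf <- switch(ph,
        accel = c("age", "sex_num", "time_diff"),
        age = c("accel", "sex_num", "time_diff"),
        c("sex_num", "time_diff"))
      extra <- if (ph %in% c("accel", "age")) score_names
               else c("accel", "age")
      variants <- list(phenotype = base_conf)
      if (config$control_adjusted) {
        variants$control_adjusted <- c(base_conf, extra)
      }
      for (vn in names(variants)) {
        cfg <- config$rcpm
        cfg$seed <- stage_seed(rseed, match(ph, config$rcpm_phenotypes)) +
          match(vn, names(variants))
        runs[[paste(ph, vn, sep = ".")]] <- rcpm(
          conn$edges, subj_fmri[[ph]],
          confounds = subj_fmri[, variants[[vn]], drop = FALSE],
          config = cfg, permutation = config$permutation,
          n_nodes = config$cohort$n_nodes)
      }
    }
    list(connectomes = conn, runs = runs, subjects = subj_fmri)
  })
  res$rcpm <- rc
  note("rcpm", rseed, lapply(rc$runs, function(r) r$cv$rho))
  if (!"importance" %in% config$stages) return(.pipeline_done(res, manifest))

  # --- importance
  iseed <- stage_seed(config$seed, "importance")
  imp <- run_stage("importance", {
    main <- rc$runs[grep("\\.phenotype$", names(rc$runs))]
    names(main) <- sub("\\.phenotype$", "", names(main))
    rep <- importance_report(main, sim$node_metadata)
    lobes <- lapply(main, function(r) {
      lobe_summary(top_fraction_edges(r$coefficients$positive),
                   top_fraction_edges(r$coefficients$negative),
                   sim$node_metadata)
    })
    list(report = rep, lobe_summaries = lobes)
  })
  res$importance <- imp
  note("importance", iseed, imp$report$tables)
  .pipeline_done(res, manifest)
}

.pipeline_done <- function(res, manifest) {
  res$manifest <- manifest
  class(res) <- "pipeline_result"
  res
}

# session-mean item matrix, one row per subject
.session_mean_items <- function(phenotypes, items) {
  agg <- aggregate(phenotypes[, items],
                   by = list(subject_id = phenotypes$subject_id), FUN = mean)
  as.matrix(agg[, items])
}

# subject-level table: covariates plus session-mean network scores
.subject_table <- function(phenotypes, scores) {
  sc <- if (inherits(scores, "network_scores")) scores$scores else scores
  df <- cbind(phenotypes[, c("subject_id", "accel", "age", "time_diff", "sex")],
              sc)
  agg <- aggregate(df[, -c(1, 5)], by = list(subject_id = df$subject_id,
                                             sex = df$sex), FUN = mean)
  agg <- agg[match(unique(df$subject_id), agg$subject_id), ]
  agg$sex_num <- as.numeric(agg$sex == "female")
  rownames(agg) <- NULL
  agg
}

# name detected communities by their anchor items where unambiguous
.label_communities <- function(typical) {
  memb <- typical$membership
  anchors <- c(proc_speed = "DigSym", memory = "Recall",
               spatial_reasoning = "MatRea", vocabulary = "Vocab")
  labs <- paste0("dim", seq_len(typical$n_communities))
  if (all(names(anchors) %in% names(battery_items())) &&
      all(anchors %in% names(memb))) {
    hit <- memb[anchors]
    if (length(unique(hit)) == length(hit)) {
      labs[hit] <- names(anchors)
    }
  }
  labs
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run:\n")
  print(x$manifest, row.names = FALSE)
  invisible(x)
}
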
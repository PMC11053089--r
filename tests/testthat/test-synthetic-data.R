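test_that("cohort generation is deterministic and orthogonalizes accel", {
  cfg <- cohort_config()
  a <- generate_cohort(cfg, seed = 7)
  b <- generate_cohort(cfg, seed = 7)
  expect_identical(a, b)

  expect_equal(nrow(a), 103L)
  expect_lt(abs(cor(a$accel, a$age)), 1e-10)
  # direct projection oracle: residuals orthogonal to [1, age]
  expect_lt(abs(sum(a$accel)), 1e-8)
  expect_lt(abs(sum(a$accel * a$age)), 1e-6)
  expect_true(all(a$age >= 59 & a$age <= 81))
  expect_setequal(unique(a$sex), c("female", "male"))
})

test_that("accel SD matches the configured 3.49 at large n", {
  co <- generate_cohort(cohort_config(n_subjects = 100000, n_fmri = 0),
                        seed = 11)
  expect_lt(abs(sd(co$accel) - 3.49) / 3.49, 0.01)
})

test_that("invalid cohort configs are rejected", {
  expect_error(cohort_config(n_subjects = 0), "n_subjects")
  expect_error(cohort_config(age_sd = -1), "age_sd")
  expect_error(cohort_config(accel_sd = 0), "accel_sd")
  expect_error(cohort_config(n_subjects = 50, n_fmri = 60), "n_fmri")
  expect_error(cohort_config(prop_female = 1.2), "prop_female")
})

test_that("noise-free battery reproduces the factor structure exactly", {
  co <- generate_cohort(cohort_config(n_subjects = 2000, n_fmri = 0), seed = 3)
  eff <- effect_config(beta_accel = rep(0, 4), beta_age = rep(0, 4),
                       beta_session = rep(0, 4), item_loading = 1,
                       item_noise_sd = 0, subject_re_sd = c(0, 0))
  bat <- generate_cognitive_battery(co, eff, seed = 4)
  items <- battery_items()
  # items within a factor are identical (same standardization of same factor)
  for (f in names(items)) {
    block <- as.matrix(bat[, items[[f]]])
    expect_lt(max(abs(block - block[, 1])), 1e-12)
  }
  # cross-factor item correlations estimate factor_corr entries
  cors <- cor(bat$DigSym, bat[, c("Recall", "MatRea", "Vocab")])
  expect_true(all(abs(cors - 0.45) < 0.05))
})

test_that("large-n OLS on generated factors recovers configured betas", {
  co <- generate_cohort(cohort_config(n_subjects = 5000, n_fmri = 0), seed = 5)
  bat <- generate_cognitive_battery(co, effect_config(), seed = 6)
  f <- attr(bat, "latent_factors")
  z <- function(x) (x - mean(x)) / sd(x)
  # closed-form OLS oracle
  X <- cbind(1, z(bat$accel), z(bat$age), bat$session)
  beta <- qr.coef(qr(X), z(f[, "proc_speed"]))
  expect_lt(abs(beta[2] - (-0.31)), 0.05)
  expect_lt(abs(beta[3] - (-0.39)), 0.05)
  beta_m <- qr.coef(qr(X), z(f[, "memory"]))
  expect_lt(abs(beta_m[2] - (-0.33)), 0.05)
})

test_that("default battery exhibits a positive manifold", {
  fx <- default_battery()
  R <- cor(session_mean_items(fx$battery))
  expect_true(all(R[upper.tri(R)] > 0))
})

test_that("battery rejects a non-positive-definite factor correlation", {
  bad <- matrix(0.99, 4, 4); bad[1, 2] <- bad[2, 1] <- -0.99; diag(bad) <- 1
  expect_error(effect_config(factor_corr = bad), "positive-definite")
})

test_that("synthetic connectomes are symmetric with calibrated signal", {
  fx <- default_battery()
  subj <- fx$cohort[fx$cohort$has_fmri, ]
  subj$memory <- rnorm(nrow(subj))   # placeholder phenotype column
  cs <- generate_connectomes(subj, connectome_signal_config(),
                             seed = 9, n_nodes = 80)
  M <- cs$matrices[[1]]
  expect_identical(M, t(M))
  expect_true(all(diag(M) == 0))
  expect_equal(dim(cs$edges), c(98L, 80 * 79 / 2))

  # empirical edge-phenotype correlations match the configured strength
  acc_edges <- cs$signal_edges[cs$signal_edges$phenotype == "accel", ]
  r <- vapply(seq_len(nrow(acc_edges)), function(k) {
    cor(cs$edges[, acc_edges$edge[k]], subj$accel) * acc_edges$sign[k]
  }, numeric(1))
  expect_lt(abs(mean(r) - 0.5), 0.1)
})

test_that("a zero-strength generator yields null edges", {
  fx <- default_battery()
  subj <- fx$cohort[fx$cohort$has_fmri, ]
  cs <- generate_connectomes(subj,
    connectome_signal_config(signal_strength = 0, phenotype_map = c(accel = 1)),
    seed = 10, n_nodes = 40)
  n <- nrow(subj)
  r <- cor(cs$edges[, seq(1, ncol(cs$edges), by = 7)], subj$accel)
  expect_lt(max(abs(r)), 3 / sqrt(n) + 0.15)
  expect_equal(nrow(cs$signal_edges), 0L)
})

test_that("connectome generator validates signal nodes and phenotypes", {
  fx <- default_battery()
  subj <- fx$cohort[fx$cohort$has_fmri, ]
  expect_error(generate_connectomes(subj,
    connectome_signal_config(signal_nodes = 1:50,
                             phenotype_map = c(accel = 1)),
    seed = 1, n_nodes = 30), "signal_nodes")
  expect_error(generate_connectomes(subj,
    connectome_signal_config(phenotype_map = c(nonexistent = 1)),
    seed = 1, n_nodes = 30), "nonexistent")
  expect_error(connectome_signal_config(signal_strength = 1.5),
               "signal_strength")
})

test_that("node metadata partitions nodes into ten lobes deterministically", {
  a <- generate_node_metadata(268, seed = 2)
  b <- generate_node_metadata(268, seed = 2)
  expect_identical(a, b)
  expect_equal(nrow(a), 268L)
  expect_equal(length(unique(a$lobe)), 10L)
  expect_equal(sum(table(a$lobe)), 268L)
  expect_true(all(a$lobe[1:20] == "Limbic"))
  expect_error(generate_node_metadata(10, seed = 1, signal_nodes = 1:20),
               "signal_nodes")
})
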
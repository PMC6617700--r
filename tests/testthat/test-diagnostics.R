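# Diagnostic classifier: scoring, training, cross-validation, transfer, noise.

test_that("patient scores are correlations with the reference direction", {
  set.seed(22)
  ref <- stats::setNames(rnorm(61), sense_codons())
  ref <- ref / sqrt(sum(ref^2))
  # a patient equal to the reference scores 1, its negation -1
  m <- cbind(pos = ref, neg = -ref)
  rownames(m) <- sense_codons()
  sc <- patient_scores(m, ref)
  expect_equal(unname(sc), c(1, -1), tolerance = 1e-12)

  # Gram-Schmidt: orthogonalize a random vector against the centered reference
  v <- rnorm(61)
  rc <- ref - mean(ref)
  vc <- v - mean(v)
  v_orth <- vc - sum(vc * rc) / sum(rc * rc) * rc
  m2 <- cbind(orth = v_orth)
  rownames(m2) <- sense_codons()
  expect_equal(unname(patient_scores(m2, ref)), 0, tolerance = 1e-10)
})

test_that("model fitting never touches held-out samples", {
  co <- default_cohort()
  cecm <- sample_cec_matrix(default_profile(), co$abundance,
                            subset = default_gp1())
  ids <- colnames(cecm)
  train <- c(ids[co$labels[ids] == "control"][1:20],
             ids[co$labels[ids] == "disease"][1:20])
  test_ids <- setdiff(ids, train)
  model <- fit_diagnostic(cecm, co$labels, train)
  poisoned <- cecm
  poisoned[, test_ids] <- matrix(rnorm(61 * length(test_ids)), 61)
  model_p <- fit_diagnostic(poisoned, co$labels, train)
  expect_identical(model$reference_direction, model_p$reference_direction)
  expect_identical(model$cutoff, model_p$cutoff)
})

test_that("scores are invariant under per-patient rescaling of abundances", {
  co <- default_cohort()
  prof <- default_profile()
  cec_a <- sample_cec_matrix(prof, co$abundance[, 1:4], transform = "raw")
  scaled <- sweep(co$abundance[, 1:4], 2, c(2, 10, 0.5, 7), `*`)
  cec_b <- sample_cec_matrix(prof, scaled, transform = "raw")
  expect_equal(cec_a, cec_b, tolerance = 1e-12)
})

test_that("cross-validated diagnostics are reproducible and class-size checked", {
  co <- default_cohort()
  prof <- default_profile()
  p1 <- cross_validated_diagnostics(prof, co$abundance, co$labels,
                                    subset = default_gp1(), n_reps = 20, seed = 5)
  p2 <- cross_validated_diagnostics(prof, co$abundance, co$labels,
                                    subset = default_gp1(), n_reps = 20, seed = 5)
  expect_identical(p1$per_rep, p2$per_rep)

  tiny_labels <- co$labels
  tiny_labels[names(tiny_labels)[tiny_labels == "disease"][-(1:2)]] <- NA
  keep <- !is.na(tiny_labels)
  expect_error(
    cross_validated_diagnostics(prof, co$abundance[, keep],
                                tiny_labels[keep], n_reps = 5, seed = 1),
    "disease")
})

test_that("the permutation null yields chance-level performance", {
  co <- default_cohort()
  perf <- cross_validated_diagnostics(default_profile(), co$abundance,
                                      co$labels, subset = default_gp1(),
                                      n_reps = 100, seed = 31,
                                      shuffle_labels = TRUE)
  expect_lt(abs(perf$sensitivity$mean - 0.5), 0.1)
  expect_lt(abs(perf$specificity$mean - 0.5), 0.1)
})

test_that("identity transfer equals resubstitution of the single fitted model", {
  co <- default_cohort()
  prof <- default_profile()
  ds <- list(profiles = prof, abundance = co$abundance, labels = co$labels)
  tr <- transfer_diagnostics(ds, ds, subset = default_gp1())
  cecm <- sample_cec_matrix(prof, co$abundance, subset = default_gp1())
  model <- fit_diagnostic(cecm, co$labels, colnames(cecm))
  resub <- evaluate_diagnostic(model, cecm, co$labels)
  expect_equal(tr$performance, resub)
})

test_that("cutoffs transfer across independently generated cohorts", {
  g <- default_genome()
  prof <- default_profile()
  co_a <- generate_cohort(g, cohort_spec(seed = 41, base_meanlog2 = 6))
  co_b <- generate_cohort(g, cohort_spec(seed = 42, base_meanlog2 = 8))
  tr <- transfer_diagnostics(
    list(profiles = prof, abundance = co_a$abundance, labels = co_a$labels),
    list(profiles = prof, abundance = co_b$abundance, labels = co_b$labels),
    subset = default_gp1())
  expect_gte(tr$performance[["sensitivity"]], 0.8)
  expect_gte(tr$performance[["specificity"]], 0.8)

  # a no-effect test cohort is classified at chance overall
  co_null <- generate_cohort(g, cohort_spec(seed = 43, beta = 0))
  tr0 <- transfer_diagnostics(
    list(profiles = prof, abundance = co_a$abundance, labels = co_a$labels),
    list(profiles = prof, abundance = co_null$abundance, labels = co_null$labels),
    subset = default_gp1())
  expect_lt(abs(mean(tr0$performance) - 0.5), 0.35)
})

test_that("fold factor one reproduces the unperturbed run exactly", {
  co <- default_cohort()
  prof <- default_profile()
  nr <- noise_robustness(prof, co$abundance, co$labels, subset = default_gp1(),
                         fold_factors = 1, n_noise_reps = 1, cv_reps = 20,
                         seed = 7)
  direct <- cross_validated_diagnostics(prof, co$abundance, co$labels,
                                        subset = default_gp1(), n_reps = 20,
                                        seed = 7)
  expect_equal(nr$sensitivity, direct$sensitivity$mean, tolerance = 1e-12)
  expect_equal(nr$specificity, direct$specificity$mean, tolerance = 1e-12)
  expect_error(noise_robustness(prof, co$abundance, co$labels,
                                fold_factors = 0.5), ">= 1")
})
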
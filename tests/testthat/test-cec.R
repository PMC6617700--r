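# Codon employment coefficients, cohort aggregation, shift, CorrCEC.

make_pct <- function(m) {
  full <- matrix(0, nrow(m), 61, dimnames = list(rownames(m), sense_codons()))
  full[, colnames(m)] <- m
  # fill the remainder so rows sum to 100 via one spill-over codon
  full[, "TTT"] <- full[, "TTT"] + (100 - rowSums(full))
  full
}

test_that("CEC is the per-codon Pearson correlation with abundance", {
  pct <- make_pct(matrix(c(0, 10, 20, 30), 4, 1,
                         dimnames = list(paste0("g", 1:4), "AAA")))
  ab <- stats::setNames(c(1, 2, 3, 4), rownames(pct))
  cec <- compute_cec(pct, ab, transform = "raw")
  expect_equal(unname(cec["AAA"]), 1)

  pct2 <- make_pct(matrix(c(2.5, 1.0, 3.0), 3, 1,
                          dimnames = list(paste0("g", 1:3), "GCC")))
  ab2 <- stats::setNames(c(10, 2, 8), rownames(pct2))
  cec2 <- compute_cec(pct2, ab2, transform = "raw")
  expect_equal(unname(cec2["GCC"]),
               pearson_naive(c(2.5, 1.0, 3.0), c(10, 2, 8)),
               tolerance = 1e-12)
  expect_equal(round(unname(cec2["GCC"]), 3), 0.885)
})

test_that("constant abundance or constant codon columns yield NA, never zero", {
  pct <- small_profile()$pct[1:10, ]
  ab <- stats::setNames(rep(5, 10), rownames(pct))
  cec <- compute_cec(pct, ab)
  expect_true(all(is.na(cec)))

  ab2 <- stats::setNames(seq_len(10), rownames(pct))
  pct_const <- pct
  pct_const[, "GCC"] <- 7
  cec2 <- compute_cec(pct_const, ab2)
  expect_true(is.na(cec2["GCC"]))
  expect_false(all(is.na(cec2)))
})

test_that("CEC agrees with the naive two-pass Pearson oracle on random instances", {
  set.seed(6)
  pct <- small_profile()$pct[1:50, ]
  for (rep in 1:5) {
    ab <- stats::setNames(rlnorm(50, 5, 1), rownames(pct))
    cec <- compute_cec(pct, ab, transform = "log2p1")
    y <- log2(1 + ab)
    for (codon in sample(sense_codons(), 8)) {
      expect_equal(unname(cec[codon]), pearson_naive(pct[, codon], y),
                   tolerance = 1e-10)
    }
  }
})

test_that("CEC is invariant under positive affine abundance transforms and gene permutation", {
  set.seed(7)
  pct <- small_profile()$pct[1:40, ]
  ab <- stats::setNames(rlnorm(40, 4, 1), rownames(pct))
  base <- compute_cec(pct, ab, transform = "raw")
  aff <- compute_cec(pct, 3.7 * ab + 11, transform = "raw")
  expect_equal(as.numeric(base), as.numeric(aff), tolerance = 1e-12)

  perm <- sample(rownames(pct))
  permuted <- compute_cec(pct[perm, ], ab[perm], transform = "raw")
  expect_equal(as.numeric(base), as.numeric(permuted), tolerance = 1e-12)
})

test_that("cohort CEC averages per-sample vectors with SEM", {
  pct <- small_profile()$pct
  ab <- stats::setNames(rlnorm(nrow(pct), 4, 1), rownames(pct))
  two <- cbind(s1 = ab, s2 = ab)
  cc <- cohort_cec(pct, two)
  single <- compute_cec(pct, ab)
  expect_equal(unname(cc$mean), as.numeric(single), tolerance = 1e-12)
  expect_equal(unname(cc$sem), rep(0, 61), tolerance = 1e-12)
  expect_error(cohort_cec(pct, two, labels = c(s1 = "control", s2 = "control"),
                          label = "disease"), "no samples")
})

test_that("random cohort halves fall on the identity line within 3 SEM", {
  co <- default_cohort()
  prof <- default_profile()
  ctrl_ids <- names(co$labels)[co$labels == "control"]
  set.seed(8)
  half1 <- sample(ctrl_ids, 12)
  half2 <- setdiff(ctrl_ids, half1)
  c1 <- cohort_cec(prof, co$abundance[, half1])
  c2 <- cohort_cec(prof, co$abundance[, half2])
  pooled_sem <- sqrt(c1$sem^2 + c2$sem^2)
  frac <- mean(abs(c1$mean - c2$mean) <= 3 * pooled_sem, na.rm = TRUE)
  expect_gte(frac, 0.95)
})

test_that("employment shift uses the absolute-value denominator and excludes near-zero controls", {
  ctrl <- stats::setNames(rep(0.5, 61), sense_codons())
  dis <- ctrl
  au3 <- au3_codons()[1]
  gc3 <- gc3_codons()[1]
  ctrl[au3] <- 0.20; dis[au3] <- 0.26
  ctrl[gc3] <- -0.40; dis[gc3] <- -0.30
  sh <- employment_shift(ctrl, dis)
  expect_equal(unname(sh$per_codon[au3]), 30, tolerance = 1e-12)
  expect_equal(unname(sh$per_codon[gc3]), 25, tolerance = 1e-12)

  # self-shift is zero everywhere
  self <- employment_shift(ctrl, ctrl)
  expect_equal(self$au3_shift_pct, 0)
  expect_equal(self$gc3_shift_pct, 0)

  # epsilon floor: a codon with |control| below epsilon is excluded and listed
  ctrl2 <- ctrl; ctrl2[au3] <- 0.001
  sh2 <- employment_shift(ctrl2, dis)
  expect_true(au3 %in% sh2$excluded)
  expect_true(is.na(sh2$per_codon[au3]))

  # a whole group excluded raises an error
  ctrl3 <- ctrl; ctrl3[au3_codons()] <- 0
  expect_error(employment_shift(ctrl3, dis), "AU3")
})

test_that("CorrCEC has the stated sign semantics and exact antisymmetry", {
  set.seed(9)
  dis <- stats::setNames(rnorm(61), sense_codons())
  ctrl <- -dis
  # a gene whose composition is a positive affine image of the disease CEC
  pct <- matrix(rep(10 + 2 * dis, 3), 3, 61, byrow = TRUE,
                dimnames = list(paste0("g", 1:3), sense_codons()))
  pct[2, ] <- pct[2, ] + rnorm(61, 0, 0.1)
  pct[3, ] <- pct[3, ] + rnorm(61, 0, 0.1)
  cc <- corrcec(pct, ctrl, dis)
  expect_equal(cc$r_disease[1], 1, tolerance = 1e-12)
  expect_equal(cc$r_control[1], -1, tolerance = 1e-12)
  expect_equal(cc$score[1], 2, tolerance = 1e-12)

  # equal cohorts: all scores zero
  same <- corrcec(pct, dis, dis)
  expect_equal(same$score, rep(0, 3))

  # swapping cohorts negates the score exactly
  swapped <- corrcec(pct, dis, ctrl)
  expect_equal(swapped$score, -cc$score, tolerance = 1e-15)

  # difference-vector scalarization is exposed
  dv <- corrcec(pct, ctrl, dis, method = "difference_vector")
  expect_equal(dv$score[1], 1, tolerance = 1e-12)
})

test_that("on the synthetic causal cohort GP1 scores are positive and GP2 negative", {
  co <- default_cohort()
  prof <- default_profile()
  ctrl <- cohort_cec(prof, co$abundance, co$labels, "control")
  dis <- cohort_cec(prof, co$abundance, co$labels, "disease")
  cc <- corrcec(prof, ctrl, dis)
  expect_gt(mean(cc$score[cc$gene_id %in% default_gp1()]), 0)
  expect_lt(mean(cc$score[cc$gene_id %in% default_gp2()]), 0)
})
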
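# Synthetic genome and cohort generator: determinism, planted structure,
# parameter recovery.

test_that("generation is fully deterministic under a seed", {
  a <- generate_cds_set(genome_spec(n_genes = 50, seed = 17))
  b <- generate_cds_set(genome_spec(n_genes = 50, seed = 17))
  expect_identical(a$cds$sequences, b$cds$sequences)
  expect_identical(a$truth, b$truth)

  fa1 <- withr::local_tempfile(fileext = ".fa")
  fa2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(a$cds, fa1)
  write_fasta(b$cds, fa2)
  expect_identical(readLines(fa1), readLines(fa2))

  co1 <- generate_cohort(a, cohort_spec(seed = 18))
  co2 <- generate_cohort(a, cohort_spec(seed = 18))
  expect_identical(co1$abundance, co2$abundance)
})

test_that("a point-mass GC3 target of 100 with 4-fold families is realized exactly", {
  spec <- genome_spec(n_genes = 5, gc3_means = 99.999, gc3_sds = 1e-9,
                      gc3_weights = 1,
                      aa_freq = c(A = 0.3, G = 0.3, P = 0.2, V = 0.2),
                      gp1_frac = 0, gp2_frac = 0, seed = 19)
  g <- generate_cds_set(spec)
  prof <- composition_profile(count_codons(g$cds), gc3_denominator = "sense")
  expect_equal(unname(prof$gc3_pct), rep(100, 5))
  expect_equal(unname(prof$au3_pct), rep(0, 5))
})

test_that("generated sequences are valid CDS with ATG start and a stop end", {
  g <- small_genome()
  seqs <- g$cds$sequences
  expect_true(all(substr(seqs, 1, 3) == "ATG"))
  last <- substring(seqs, nchar(seqs) - 2)
  expect_true(all(last %in% stop_codons()))
  expect_true(all(nchar(seqs) %% 3 == 0))
})

test_that("planted groups come from the opposite composition tails", {
  truth <- default_genome()$truth
  expect_equal(sum(truth$gp1), 300)
  expect_equal(sum(truth$gp2), 300)
  expect_false(any(truth$gp1 & truth$gp2))
  expect_lt(max(truth$realized_gc3_pct[truth$gp1]), 50)
  expect_gt(min(truth$realized_gc3_pct[truth$gp2]), 50)
})

test_that("control abundances favor GC3-rich transcripts by construction", {
  co <- default_cohort()
  ctrl <- cohort_cec(default_profile(), co$abundance, co$labels, "control")
  expect_gt(mean(ctrl$mean[gc3_codons()], na.rm = TRUE), 0)
  expect_lt(mean(ctrl$mean[au3_codons()], na.rm = TRUE), 0)
})

test_that("a fully degenerate cohort flags undefined CECs downstream", {
  g <- small_genome()
  co <- generate_cohort(g, cohort_spec(beta = 0, control_gc3_coupling = 0,
                                       noise_sd = 0, tissue_factor_sd = 0,
                                       seed = 20))
  # all samples identical and abundance constant across genes only in signal:
  # baseline still varies per gene, so columns are identical vectors
  expect_equal(co$abundance[, 1], co$abundance[, ncol(co$abundance)])
  # a constant column yields all-NA CEC (degenerate-input contract)
  const <- stats::setNames(rep(3, nrow(co$abundance)), rownames(co$abundance))
  expect_true(all(is.na(compute_cec(composition_profile(count_codons(g$cds)),
                                    const))))
})

test_that("the causal beta is recovered by regression on AU3 content", {
  g <- default_genome()
  au3 <- stats::setNames(g$truth$realized_au3_pct, g$truth$gene_id)
  ests <- vapply(1:5, function(s) {
    co <- generate_cohort(g, cohort_spec(seed = s))
    lfc <- rowMeans(log2(co$abundance[, co$labels == "disease"])) -
      rowMeans(log2(co$abundance[, co$labels == "control"]))
    x <- (au3[rownames(co$abundance)] - mean(au3)) / 100
    unname(stats::coef(stats::lm(lfc ~ x))[2])
  }, numeric(1L))
  expect_lt(abs(mean(ests) - 8), 2 * stats::sd(ests) / sqrt(length(ests)) + 0.2)
})
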
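# GC3 ranking, running-sum enrichment, permutation null, BH FDR, groups.

test_that("GC3 ranking is the log2 ratio to the mean with deterministic ties", {
  gc3 <- c(a = 58.30, b = 58.30)
  r <- rank_by_gc3(gc3)
  expect_equal(r$score, c(0, 0))
  expect_equal(r$gene_id, c("a", "b"))  # lexicographic tie-break

  gc3b <- c(hi = 80, lo = 40, mid = 60)
  rb <- rank_by_gc3(gc3b)
  expect_equal(rb$gene_id, c("hi", "mid", "lo"))
  expect_equal(rb$score, c(log2(80 / 60), 0, log2(40 / 60)), tolerance = 1e-12)

  # doubling every value leaves scores unchanged
  expect_equal(rank_by_gc3(gc3b * 2)$score, rb$score, tolerance = 1e-12)

  # non-positive values are excluded with a warning
  expect_warning(rz <- rank_by_gc3(c(a = 50, b = 0, c = 60)), "non-positive")
  expect_equal(nrow(rz), 2)
})

test_that("enrichment scores match the naive running-sum walk and fgsea", {
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    scores <- sort(rnorm(n), decreasing = TRUE)
    k <- sample(3:8, 1)
    pos <- sort(sample(n, k))
    obs <- codonshift:::running_sum_es(scores, pos)$es
    expect_equal(obs, es_naive(scores, pos), tolerance = 1e-12)
    expect_equal(obs, codonshift:::es_at_hits(scores, pos), tolerance = 1e-12)
    expect_equal(obs, fgsea::calcGseaStat(scores, pos, gseaParam = 1),
                 tolerance = 1e-10)
  }
})

test_that("a set at the top of the list attains the maximal ES with exact enumerated p", {
  ranked <- data.frame(gene_id = letters[1:10], score = rep(0.5, 10))
  sets <- list(top = c("a", "b", "c"))
  res <- preranked_enrichment(ranked, sets, min_size = 3, seed = 1)
  expect_equal(res$es, 1)
  # exact null: only {1,2,3} and {8,9,10} reach |ES| = 1 among C(10,3) = 120
  null_es <- es_null_exhaustive(ranked$score, 3)
  expect_equal(res$p_perm, mean(abs(null_es) >= 1 - 1e-12))
  expect_equal(res$p_perm, 2 / 120, tolerance = 1e-12)
})

test_that("reversing the ranked list negates every ES", {
  set.seed(11)
  n <- 40
  scores <- sort(rnorm(n), decreasing = TRUE)
  for (rep in 1:10) {
    pos <- sort(sample(n, 6))
    es <- codonshift:::es_at_hits(scores, pos)
    es_rev <- codonshift:::es_at_hits(rev(-scores), sort(n + 1 - pos))
    expect_equal(es_rev, -es, tolerance = 1e-12)
  }
})

test_that("permutation p-values are uniform under the null", {
  set.seed(12)
  n_lists <- 1000
  p <- vapply(seq_len(n_lists), function(i) {
    scores <- sort(rnorm(10), decreasing = TRUE)
    ranked <- data.frame(gene_id = letters[1:10], score = scores)
    members <- sample(letters[1:10], 3)
    preranked_enrichment(ranked, list(s = members), min_size = 3,
                         seed = i)$p_perm
  }, numeric(1L))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("BH FDR equals the brute-force step-up and keeps p-ordering", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.05), 0.05)
  set.seed(13)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_stepup(p), tolerance = 1e-12)
    expect_true(max(q) <= 1)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("group derivation splits significant sets by enrichment sign", {
  res <- data.frame(set_id = c("neg", "pos", "ns"),
                    size = c(2, 2, 2),
                    es = c(-0.8, 0.7, 0.5),
                    nes = c(-2, 2, 1),
                    p_perm = c(0.001, 0.001, 0.5),
                    fdr_bh = c(0.003, 0.003, 0.5),
                    direction = c("au3_enriched", "gc3_enriched", "gc3_enriched"))
  res$leading_edge <- list(c("a", "b"), c("c", "d"), c("e"))
  gr <- derive_groups(res, fdr_cut = 0.01)
  expect_equal(gr$gp1, c("a", "b"))
  expect_equal(gr$gp2, c("c", "d"))

  # impossible threshold empties both groups
  expect_message(gr0 <- derive_groups(res, fdr_cut = 0), "empty")
  expect_equal(lengths(gr0), c(gp1 = 0L, gp2 = 0L))

  # overlap between the groups is excluded from both with a warning
  res$leading_edge <- list(c("a", "b"), c("b", "d"), "e")
  expect_warning(gr2 <- derive_groups(res, fdr_cut = 0.01), "both groups")
  expect_equal(gr2$gp1, "a")
  expect_equal(gr2$gp2, "d")
})

test_that("planted GP1/GP2 structure is recovered from the enrichment", {
  enr <- preranked_enrichment(rank_by_gc3(default_profile()), default_sets(),
                              n_perm = 1000, seed = 1)
  gr <- derive_groups(enr, fdr_cut = 0.01)
  expect_gte(jaccard(gr$gp1, default_gp1()), 0.8)
  expect_gte(jaccard(gr$gp2, default_gp2()), 0.8)
  # direction labels match the sign of the planted composition
  expect_true(all(enr$direction[grepl("^gp1", enr$set_id)] == "au3_enriched"))
  expect_true(all(enr$direction[grepl("^gp2", enr$set_id)] == "gc3_enriched"))
})

test_that("zero perturbation reproduces the unperturbed significant-set count", {
  g <- small_genome()
  prof <- composition_profile(count_codons(g$cds))
  sets <- generate_gene_sets(g$truth, n_gp1_sets = 2, n_gp2_sets = 2,
                             n_random_sets = 2, seed = 14)
  enr <- preranked_enrichment(rank_by_gc3(prof), sets, n_perm = 300, seed = 15)
  base_count <- sum(enr$fdr_bh < 0.01, na.rm = TRUE)
  rb <- perturbation_robustness(prof, sets, deltas = 0, n_reps = 5,
                                n_perm = 300, seed = 15)
  expect_equal(rb$surviving_sets, base_count)
  expect_error(perturbation_robustness(prof, sets, deltas = -1), "non-negative")
})
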
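# Composition-level statistics: parsing, counting, GC3/AU3 conventions,
# per-amino-acid fractions, RSCU.

test_that("FASTA parsing normalizes RNA and case and validates frame", {
  path <- write_temp_fasta(list(g1 = "ATGGCCAAATAA",
                                g2 = "auggccaaauaa",
                                g3 = "ATGGCCAAAT"))
  cds <- read_cds(path, policy = "strict")
  expect_identical(unname(cds$sequences["g1"]), unname(cds$sequences["g2"]))
  expect_equal(nchar(cds$sequences[["g1"]]) / 3, 4)
  expect_equal(cds$rejected$gene_id, "g3")
  expect_match(cds$rejected$reason, "multiple of 3")

  lenient <- read_cds(path, policy = "lenient")
  expect_equal(nchar(lenient$sequences[["g3"]]), 9)
})

test_that("ambiguity codes are rejected under strict and dropped under lenient", {
  path <- write_temp_fasta(list(g1 = "ATGGNCAAATAA", g2 = "ATGGCCAAATAA"))
  strict <- read_cds(path, policy = "strict")
  expect_equal(strict$rejected$gene_id, "g1")
  lenient <- read_cds(path, policy = "lenient")
  # the triplet containing N is dropped, the rest kept
  expect_equal(nchar(lenient$sequences[["g1"]]), 9)
})

test_that("duplicate ids keep the first record with a warning, empty input errors", {
  path <- write_temp_fasta(list(g1 = "ATGGCCAAATAA", g1 = "GCCGCC"))
  expect_warning(cds <- read_cds(path), "duplicate")
  expect_equal(nchar(cds$sequences[["g1"]]), 12)

  bad <- write_temp_fasta(list(g1 = "ATGGCCAAAT"))
  expect_error(read_cds(bad, policy = "strict"), "no valid")
})

test_that("codon counting enumerates frame-0 triplets and conserves totals", {
  counts <- count_codons(c(g1 = "ATGGCCAAATAA", g2 = "GCCGCC"))
  expect_equal(counts["g1", c("ATG", "GCC", "AAA", "TAA")], c(ATG = 1L, GCC = 1L, AAA = 1L, TAA = 1L))
  expect_equal(sum(counts["g1", ]), 4L)
  expect_equal(counts["g2", "GCC"], 2L, ignore_attr = TRUE)
  expect_equal(sum(counts["g2", stop_codons()]), 0L)

  # conservation across a generated gene set
  g <- small_genome()
  cm <- count_codons(g$cds)
  expect_equal(unname(rowSums(cm)), unname(nchar(g$cds$sequences) / 3))
})

test_that("composition percentages close to 100 and follow the stop-inclusive convention", {
  counts <- counts_from_list(c(ATG = 1, GCC = 1, AAA = 1, TAA = 1))
  prof <- composition_profile(counts)
  expect_equal(unname(prof$pct["g1", c("ATG", "GCC", "AAA")]), rep(100 / 3, 3))
  expect_equal(unname(prof$gc3_pct), 50)   # ATG + GCC of 4 total codons
  expect_equal(unname(prof$au3_pct), 25)   # AAA only; the stop is excluded

  pure <- composition_profile(counts_from_list(c(GCC = 7)))
  expect_equal(unname(pure$gc3_pct), 100)
  expect_equal(unname(pure$au3_pct), 0)

  g <- small_genome()
  prof <- composition_profile(count_codons(g$cds))
  expect_lt(max(abs(rowSums(prof$pct) - 100)), 1e-9)
  closure <- prof$gc3_pct + prof$au3_pct + 100 * prof$n_stop / prof$n_codons
  expect_lt(max(abs(closure - 100)), 1e-9)
})

test_that("the VAMP2-composition anchor fixture reproduces 85/117 and 31/117", {
  cds <- read_cds(vamp2_fixture_path())
  prof <- composition_profile(count_codons(cds))
  expect_equal(unname(prof$n_codons), 117)
  expect_equal(unname(prof$gc3_pct), 85 / 117 * 100, tolerance = 1e-12)
  expect_equal(unname(prof$au3_pct), 31 / 117 * 100, tolerance = 1e-12)
  # printed two-decimal values
  expect_equal(round(unname(prof$gc3_pct), 2), 72.65)
  expect_equal(round(unname(prof$au3_pct), 2), 26.50)
})

test_that("sense-only GC3 denominator is exposed as an option", {
  counts <- counts_from_list(c(ATG = 1, GCC = 1, AAA = 1, TAA = 1))
  prof <- composition_profile(counts, gc3_denominator = "sense")
  expect_equal(unname(prof$gc3_pct), 2 / 3 * 100)
  expect_equal(unname(prof$au3_pct + prof$gc3_pct), 100)
})

test_that("per-amino-acid fractions sum to one per present family and are NA otherwise", {
  frac <- per_aa_fractions(counts_from_list(c(GCC = 3, GCA = 1)))
  expect_equal(unname(frac["g1", c("GCC", "GCA")]), c(0.75, 0.25))
  expect_true(all(is.na(frac["g1", c("AAA", "TGG")])))

  frac_m <- per_aa_fractions(counts_from_list(c(ATG = 2)))
  expect_equal(unname(frac_m["g1", "ATG"]), 1)

  frac_u <- per_aa_fractions(counts_from_list(c(GCC = 1, GCG = 1, GCA = 1, GCT = 1)))
  expect_equal(unname(frac_u["g1", c("GCA", "GCC", "GCG", "GCT")]), rep(0.25, 4))

  # family closure across a generated set
  fr <- per_aa_fractions(count_codons(small_genome()$cds))
  for (fam in codon_families()) {
    sums <- rowSums(fr[, fam, drop = FALSE])
    expect_true(all(is.na(sums) | abs(sums - 1) < 1e-9))
  }
})

test_that("RSCU matches the direct formula and averages to one per family", {
  ala <- c(GCA = 2, GCC = 2, GCG = 2, GCT = 2)
  expect_equal(unname(rscu(counts_from_list(ala))[names(ala)]), rep(1, 4))

  excl <- rscu(counts_from_list(c(GCA = 4)))
  expect_equal(unname(excl[c("GCA", "GCC", "GCG", "GCT")]), c(4, 0, 0, 0))

  mixed <- rscu(counts_from_list(c(GCA = 2, GCC = 1, GCG = 1, GCT = 0)))
  expect_equal(unname(mixed[c("GCA", "GCC", "GCG", "GCT")]), c(2, 1, 1, 0))

  # absent family is missing, not zero
  expect_true(all(is.na(mixed[c("AAA", "AAG")])))

  # family means equal 1 for every family with non-zero total
  r <- rscu(count_codons(small_genome()$cds))
  for (fam in codon_families()) {
    if (all(is.na(r[fam]))) next
    expect_equal(mean(r[fam]), 1, tolerance = 1e-12)
  }
})
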
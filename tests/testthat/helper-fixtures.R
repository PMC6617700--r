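# Shared fixtures, built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# default synthetic genome (the study conditions) plus derived objects
default_genome <- function() cached("genome", function() {
  generate_cds_set(genome_spec(seed = 1))
})

default_profile <- function() cached("profile", function() {
  composition_profile(count_codons(default_genome()$cds))
})

default_gp1 <- function() {
  truth <- default_genome()$truth
  truth$gene_id[truth$gp1]
}

default_gp2 <- function() {
  truth <- default_genome()$truth
  truth$gene_id[truth$gp2]
}

default_sets <- function() cached("sets", function() {
  generate_gene_sets(default_genome()$truth, seed = 101)
})

default_cohort <- function() cached("cohort", function() {
  generate_cohort(default_genome(), cohort_spec(seed = 2))
})

# small genome for cheap unit tests
small_genome <- function() cached("small_genome", function() {
  generate_cds_set(genome_spec(n_genes = 200, seed = 3))
})

small_profile <- function() cached("small_profile", function() {
  composition_profile(count_codons(small_genome()$cds))
})

# a count matrix from explicit codon counts
counts_from_list <- function(counts, gene_id = "g1") {
  m <- matrix(0L, 1L, 64L, dimnames = list(gene_id, sort(names(Biostrings::GENETIC_CODE))))
  m[1L, names(counts)] <- as.integer(counts)
  class(m) <- c("codon_counts", class(m))
  m
}

vamp2_fixture_path <- function() {
  system.file("extdata", "vamp2_like_synthetic.fa", package = "codonshift")
}

write_temp_fasta <- function(records) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  lines <- unlist(lapply(names(records), function(id) c(paste0(">", id), records[[id]])))
  writeLines(lines, path)
  path
}
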
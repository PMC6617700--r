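# Synthetic genomes and cohorts with known ground truth.
#
# The generator emulates the statistical structure the analysis assumes: a
# bimodal per-gene GC3 distribution (two components echoing the human peaks
# near 70% and 30-40% GC3), two functionally opposed planted gene groups
# (AU3-rich GP1, GC3-rich GP2), control abundances in which GC3-rich
# transcripts are favored, and disease abundances produced by a graded,
# composition-dependent (causal) shift toward AU3-rich transcripts.

# human-like amino-acid frequencies (fractions, approximate proteome averages)
HUMAN_AA_FREQ <- c(
  A = 0.070, R = 0.056, N = 0.036, D = 0.047, C = 0.023,
  Q = 0.048, E = 0.071, G = 0.066, H = 0.026, I = 0.043,
  L = 0.100, K = 0.057, M = 0.021, F = 0.037, P = 0.063,
  S = 0.083, T = 0.053, W = 0.012, Y = 0.027, V = 0.060
)

#' Specification of a synthetic genome
#'
#' Defaults are the study conditions of the package's validation pipeline: a
#' two-component GC3 mixture with means 35 and 70 percentage points (SD 6,
#' weights 0.4 / 0.6), log-normal codon counts around a few hundred codons,
#' human-like amino-acid frequencies, and 15% of genes planted into each of
#' the AU3-rich (GP1, drawn from the low-GC3 component) and GC3-rich (GP2,
#' high component) groups.
#'
#' @param n_genes Number of genes (default 2000).
#' @param length_meanlog,length_sdlog Log-normal parameters of the per-gene
#'   sense codon count (defaults `log(350)`, 0.35; floored at 30 codons).
#' @param gc3_means,gc3_sds,gc3_weights Mixture components of the per-gene
#'   target GC3 percentage.
#' @param aa_freq Named amino-acid sampling frequencies (normalized
#'   internally).
#' @param gp1_frac,gp2_frac Fractions of genes planted into GP1 / GP2.
#' @param seed Integer seed.
#' @return List of class `genome_spec`.
#' @export
genome_spec <- function(n_genes = 2000,
                        length_meanlog = log(350), length_sdlog = 0.35,
                        gc3_means = c(35, 70), gc3_sds = c(6, 6),
                        gc3_weights = c(0.4, 0.6),
                        aa_freq = HUMAN_AA_FREQ,
                        gp1_frac = 0.15, gp2_frac = 0.15,
                        seed = 1) {
  stopifnot(n_genes >= 2, length(gc3_means) == length(gc3_sds),
            length(gc3_means) == length(gc3_weights),
            abs(sum(gc3_weights) - 1) < 1e-9,
            all(gc3_means > 0 & gc3_means < 100),
            gp1_frac >= 0, gp2_frac >= 0, gp1_frac + gp2_frac <= 1)
  structure(list(n_genes = n_genes, length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog, gc3_means = gc3_means,
                 gc3_sds = gc3_sds, gc3_weights = gc3_weights,
                 aa_freq = aa_freq / sum(aa_freq),
                 gp1_frac = gp1_frac, gp2_frac = gp2_frac,
                 seed = seed),
            class = "genome_spec")
}

# per-family third-base ending classes
family_ending_classes <- function() {
  lapply(AA_FAMILIES, function(fam) {
    list(gc = fam[third_base(fam) %in% c("G", "C")],
         au = fam[third_base(fam) %in% c("A", "T")])
  })
}

#' Generate a synthetic CDS set with planted composition structure
#'
#' Per gene: a target GC3 percentage is drawn from the mixture, an
#' amino-acid sequence from `aa_freq` (ATG first, a uniformly drawn stop
#' codon appended), and each synonymous codon's third-base class is chosen
#' G/C-ending with probability equal to the target (restricted to the
#' family's available ending classes; single-class families such as Met use
#' the nearest feasible class). GP1 genes are drawn from the lowest-mean
#' mixture component, GP2 genes from the highest.
#'
#' @param spec A `genome_spec`.
#' @return List with `cds` (a `cds_set`) and `truth` (data frame with
#'   columns `gene_id`, `component`, `target_gc3`, `n_codons`,
#'   `realized_gc3_pct`, `realized_au3_pct`, `gp1`, `gp2`), plus `spec`.
#' @export
generate_cds_set <- function(spec = genome_spec()) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(as.integer(spec$seed %% .Machine$integer.max))
  n <- spec$n_genes
  ids <- sprintf("g%05d", seq_len(n))
  comp <- sample.int(length(spec$gc3_weights), n, replace = TRUE,
                     prob = spec$gc3_weights)
  target <- pmin(pmax(stats::rnorm(n, spec$gc3_means[comp], spec$gc3_sds[comp]),
                      0), 100)
  n_sense_codons <- pmax(30L, round(stats::rlnorm(n, spec$length_meanlog,
                                                  spec$length_sdlog)))
  classes <- family_ending_classes()
  aas <- names(spec$aa_freq)

  # body amino acids for all genes at once (first codon is ATG, then body,
  # then a stop codon)
  body_len <- n_sense_codons - 1L
  gene_of <- rep.int(seq_len(n), body_len)
  total <- length(gene_of)
  aa_all <- sample(aas, total, replace = TRUE, prob = spec$aa_freq)
  # Met and Trp are always G-ending; compensate the class probability of the
  # degenerate families so the realized sense GC3 matches the drawn target
  f_single <- sum(spec$aa_freq[names(spec$aa_freq) %in% c("M", "W")])
  p_gc <- pmin(pmax((target / 100 - f_single) / (1 - f_single), 0), 1)[gene_of]
  want_gc <- stats::runif(total) < p_gc
  codon_all <- character(total)
  for (aa in aas) {
    cls <- classes[[aa]]
    sel <- which(aa_all == aa)
    if (length(sel) == 0L) next
    use_gc <- want_gc[sel]
    # infeasible targets fall back to the family's only ending class
    if (length(cls$gc) == 0L) use_gc[] <- FALSE
    if (length(cls$au) == 0L) use_gc[] <- TRUE
    g <- sel[use_gc]
    a <- sel[!use_gc]
    if (length(g) > 0L) codon_all[g] <- sample(cls$gc, length(g), replace = TRUE)
    if (length(a) > 0L) codon_all[a] <- sample(cls$au, length(a), replace = TRUE)
  }
  stops <- sample(STOP_CODONS, n, replace = TRUE)
  bodies <- vapply(split(codon_all, factor(gene_of, levels = seq_len(n))),
                   paste, character(1L), collapse = "")
  seqs <- stats::setNames(paste0("ATG", bodies, stops), ids)
  cds <- cds_from_strings(seqs, policy = "strict")

  prof <- composition_profile(count_codons(cds))
  # planted groups emulate genes *significantly* de-enriched / enriched in
  # GC3: they are drawn from the outer half of the low / high component, not
  # uniformly from it
  low <- which.min(spec$gc3_means)
  high <- which.max(spec$gc3_means)
  low_pool <- ids[comp == low &
                    target <= stats::median(target[comp == low])]
  high_pool <- ids[comp == high &
                     target >= stats::median(target[comp == high])]
  gp1 <- plant_group(low_pool, round(spec$gp1_frac * n))
  gp2 <- plant_group(high_pool, round(spec$gp2_frac * n))
  truth <- data.frame(gene_id = ids, component = comp, target_gc3 = target,
                      n_codons = n_sense_codons + 1L,
                      realized_gc3_pct = as.numeric(prof$gc3_pct[ids]),
                      realized_au3_pct = as.numeric(prof$au3_pct[ids]),
                      gp1 = ids %in% gp1, gp2 = ids %in% gp2)
  list(cds = cds, truth = truth, spec = spec)
}

plant_group <- function(pool, size) {
  if (size > length(pool)) size <- length(pool)
  sort(sample(pool, size))
}

#' Planted gene-set collection for enrichment validation
#'
#' Builds a GMT-style named list of gene sets from a genome ground truth:
#' the planted GP1 genes are partitioned across `n_gp1_sets` sets (likewise
#' GP2), each contaminated with a fraction of genes drawn from the remaining
#' genome, plus purely random background sets. Recovering the planted groups
#' from these sets is the enrichment module's validation target.
#'
#' @param truth Ground-truth data frame from [generate_cds_set()].
#' @param n_gp1_sets,n_gp2_sets Number of sets covering each planted group
#'   (default 5 each).
#' @param n_random_sets Number of background sets (default 10).
#' @param random_set_size Size of each background set (default 50).
#' @param contamination Fraction of extra random genes added to each planted
#'   set (default 0.2).
#' @param seed Integer seed.
#' @return Named list of character vectors of gene ids.
#' @export
generate_gene_sets <- function(truth, n_gp1_sets = 5, n_gp2_sets = 5,
                               n_random_sets = 10, random_set_size = 50,
                               contamination = 0.2, seed = 1) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  ids <- truth$gene_id
  gp1 <- ids[truth$gp1]
  gp2 <- ids[truth$gp2]
  other <- setdiff(ids, c(gp1, gp2))
  planted_sets <- function(members, n_sets, tag) {
    if (n_sets == 0L || length(members) == 0L) return(list())
    part <- split(sample(members), rep_len(seq_len(n_sets), length(members)))
    out <- lapply(part, function(m) {
      n_extra <- round(contamination * length(m))
      sort(c(m, sample(other, n_extra)))
    })
    stats::setNames(out, sprintf("%s_set_%02d", tag, seq_len(n_sets)))
  }
  sets <- c(planted_sets(gp1, n_gp1_sets, "gp1"),
            planted_sets(gp2, n_gp2_sets, "gp2"))
  if (n_random_sets > 0L) {
    rnd <- lapply(seq_len(n_random_sets), function(i) {
      sort(sample(ids, min(random_set_size, length(ids) - 1L)))
    })
    sets <- c(sets, stats::setNames(rnd, sprintf("random_set_%02d",
                                                 seq_len(n_random_sets))))
  }
  sets
}

#' Specification of a synthetic control/disease cohort
#'
#' Control samples draw per-gene log2 abundances around a shared baseline
#' with a positive GC3 coupling (GC3-rich transcripts are favored in the
#' control state); disease samples additionally shift every gene in
#' proportion to its AU3 percentage (the causal codon-employment-shift
#' model). Per-patient multiplicative noise is log-normal. A per-patient
#' "tissue composition" factor applied coherently to the GP2
#' (differentiation-program) genes in every sample emulates the
#' biopsy-to-biopsy cellular-composition variability of real cohorts; set
#' `tissue_factor_sd = 0` for a fully homogeneous cohort.
#'
#' The `effect` argument selects the bundled presets: `"strong"`
#' (`beta = 8`, the high-performance diagnostic regime) or `"weak"`
#' (`beta = 1`, a subtle shift near the clinical 85% regime).
#'
#' @param n_control,n_disease Sample counts (defaults 25 / 25).
#' @param base_meanlog2,base_sdlog2 Per-gene baseline log2 abundance
#'   distribution (defaults 6, 2).
#' @param control_gc3_coupling Log2-fold units per 100 GC3 percentage points
#'   in control samples (default 8).
#' @param beta Causal AU3 coefficient of the disease state, log2-fold units
#'   per 100 AU3 percentage points (default set by `effect`).
#' @param noise_sd Per-gene, per-sample log2 noise SD (default 0.5).
#' @param tissue_factor_sd SD of the per-patient log2 factor applied to GP2
#'   genes (default 1).
#' @param effect Preset, `"strong"` or `"weak"`; only used when `beta` is
#'   NULL.
#' @param seed Integer seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 25, n_disease = 25,
                        base_meanlog2 = 6, base_sdlog2 = 2,
                        control_gc3_coupling = 8, beta = NULL,
                        noise_sd = 0.5, tissue_factor_sd = 1,
                        effect = c("strong", "weak"), seed = 1) {
  effect <- match.arg(effect)
  if (is.null(beta)) beta <- switch(effect, strong = 8, weak = 1.5)
  stopifnot(n_control >= 2, n_disease >= 2, noise_sd >= 0,
            tissue_factor_sd >= 0, is.finite(beta))
  structure(list(n_control = n_control, n_disease = n_disease,
                 base_meanlog2 = base_meanlog2, base_sdlog2 = base_sdlog2,
                 control_gc3_coupling = control_gc3_coupling, beta = beta,
                 noise_sd = noise_sd, tissue_factor_sd = tissue_factor_sd,
                 effect = effect, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic control/disease abundance cohort
#'
#' @param genome Output of [generate_cds_set()] (its `truth` is used), or a
#'   ground-truth data frame.
#' @param spec A `cohort_spec`.
#' @return List with `abundance` (genes x samples matrix, linear scale),
#'   `labels` (named character vector, "control"/"disease"), and `truth`
#'   (list with the spec, the per-gene baseline, true log2 fold changes and
#'   the per-sample tissue factors).
#' @export
generate_cohort <- function(genome, spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  truth <- if (is.data.frame(genome)) genome else genome$truth
  set.seed(as.integer(spec$seed %% .Machine$integer.max))
  ids <- truth$gene_id
  n_genes <- length(ids)
  gc3 <- truth$realized_gc3_pct
  au3 <- truth$realized_au3_pct
  base <- stats::rnorm(n_genes, spec$base_meanlog2, spec$base_sdlog2)
  ctrl_signal <- spec$control_gc3_coupling * (gc3 - mean(gc3)) / 100
  dis_extra <- spec$beta * (au3 - mean(au3)) / 100
  n_s <- spec$n_control + spec$n_disease
  sample_ids <- c(sprintf("ctrl_%02d", seq_len(spec$n_control)),
                  sprintf("dis_%02d", seq_len(spec$n_disease)))
  labels <- stats::setNames(rep(c("control", "disease"),
                                c(spec$n_control, spec$n_disease)), sample_ids)
  tissue <- stats::rnorm(n_s, 0, spec$tissue_factor_sd)
  gp2_mask <- as.numeric(truth$gp2)
  log2_abund <- matrix(0, n_genes, n_s, dimnames = list(ids, sample_ids))
  for (s in seq_len(n_s)) {
    mu <- base + ctrl_signal +
      (if (labels[s] == "disease") dis_extra else 0) +
      tissue[s] * gp2_mask
    log2_abund[, s] <- mu + stats::rnorm(n_genes, 0, spec$noise_sd)
  }
  list(abundance = 2^log2_abund, labels = labels,
       truth = list(spec = spec, baseline_log2 = stats::setNames(base, ids),
                    true_log2fc = stats::setNames(dis_extra, ids),
                    tissue_factor = stats::setNames(tissue, sample_ids)))
}
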
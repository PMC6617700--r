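# Codon employment coefficient (CEC) statistics.
#
# The CEC of a codon, in one sample, is the Pearson correlation across genes
# between the codon's percentage in each transcript's composition and the
# transcript's abundance. High positive CEC: the codon is over-represented in
# abundant transcripts ("employed"); negative: it sits in low-abundance ones.

#' Codon employment coefficients for one sample
#'
#' For each of the 61 sense codons, the Pearson correlation across genes
#' between the codon's composition percentage and the transcript abundance of
#' one sample. Abundances are log2(1 + x) transformed by default; the CEC is
#' invariant under positive affine transforms of the (transformed) abundance.
#'
#' @param profiles A `composition_profile` (see [composition_profile()]) or a
#'   genes x 61 percentage matrix.
#' @param abundance Named numeric vector of non-negative abundances; names are
#'   gene ids and are intersected with the profile genes.
#' @param subset Optional character vector of gene ids restricting the
#'   correlation to a gene subset (e.g. GP1).
#' @param transform `"log2p1"` (default) or `"raw"`.
#' @return Named numeric vector of 61 coefficients (`cec_vector`); codons
#'   with zero variance (or a constant abundance vector) are NA. Attributes:
#'   `n_genes`, `transform`.
#' @export
compute_cec <- function(profiles, abundance, subset = NULL,
                        transform = c("log2p1", "raw")) {
  transform <- match.arg(transform)
  pct <- profile_pct(profiles)
  if (is.null(names(abundance))) stop("abundance must be a named vector")
  if (any(!is.finite(abundance))) stop("abundance must be finite")
  genes <- intersect(rownames(pct), names(abundance))
  if (!is.null(subset)) genes <- intersect(genes, subset)
  if (length(genes) < 3L) stop("fewer than 3 shared genes after subsetting")
  y <- abundance[genes]
  if (transform == "log2p1") {
    if (any(y < 0)) stop("negative abundances cannot be log-transformed")
    y <- log2(1 + y)
  }
  r <- as.numeric(suppressWarnings(stats::cor(pct[genes, , drop = FALSE], y)))
  names(r) <- colnames(pct)
  attr(r, "n_genes") <- length(genes)
  attr(r, "transform") <- transform
  class(r) <- c("cec_vector", "numeric")
  r
}

profile_pct <- function(profiles) {
  if (inherits(profiles, "composition_profile")) return(profiles$pct)
  m <- as.matrix(profiles)
  if (is.null(rownames(m))) stop("percentage matrix must have gene id rownames")
  m
}

#' Per-sample CEC vectors for a whole abundance matrix
#'
#' @inheritParams compute_cec
#' @param abundance Genes x samples numeric matrix with dimnames.
#' @return 61 x samples matrix of CECs.
#' @export
sample_cec_matrix <- function(profiles, abundance, subset = NULL,
                              transform = c("log2p1", "raw")) {
  transform <- match.arg(transform)
  vapply(colnames(abundance), function(s) {
    as.numeric(compute_cec(profiles, abundance[, s], subset = subset,
                           transform = transform))
  }, numeric(length(SENSE_CODONS))) -> m
  rownames(m) <- SENSE_CODONS
  m
}

#' Cohort-level CEC: per-sample coefficients averaged
#'
#' Computes a CEC vector per sample of the requested label and aggregates:
#' mean and standard error (sd / sqrt(n)) per codon, with per-sample NA
#' entries excluded pairwise.
#'
#' @inheritParams sample_cec_matrix
#' @param labels Named character vector mapping sample ids to labels
#'   (e.g. "control" / "disease"); may be NULL to pool all columns.
#' @param label Label selecting the cohort; ignored when `labels` is NULL.
#' @return List of class `cohort_cec`: `mean`, `sem`, `n_defined` (61-entry
#'   vectors), `n_samples`, `per_sample` (61 x n matrix), `label`.
#' @export
cohort_cec <- function(profiles, abundance, labels = NULL, label = NULL,
                       subset = NULL, transform = c("log2p1", "raw")) {
  transform <- match.arg(transform)
  cols <- colnames(abundance)
  if (!is.null(labels)) {
    if (is.null(label)) stop("label required when labels are given")
    cols <- cols[!is.na(labels[cols]) & labels[cols] == label]
    if (length(cols) == 0L) stop("no samples with label '", label, "'")
  }
  if (length(cols) < 2L) stop("need at least 2 samples for a cohort CEC")
  per_sample <- sample_cec_matrix(profiles, abundance[, cols, drop = FALSE],
                                  subset = subset, transform = transform)
  n_def <- rowSums(!is.na(per_sample))
  mean_r <- rowMeans(per_sample, na.rm = TRUE)
  mean_r[n_def == 0L] <- NA_real_
  sem <- apply(per_sample, 1L, stats::sd, na.rm = TRUE) / sqrt(pmax(n_def, 1L))
  sem[n_def == 0L] <- NA_real_
  structure(list(mean = mean_r, sem = sem, n_defined = n_def,
                 n_samples = length(cols), per_sample = per_sample,
                 label = label %||% "all"),
            class = "cohort_cec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohort_cec <- function(x, ...) {
  cat(sprintf("cohort_cec (%s): %d samples, mean CEC over GC3 = %.3f, over AU3 = %.3f\n",
              x$label, x$n_samples,
              mean(x$mean[GC3_CODONS], na.rm = TRUE),
              mean(x$mean[AU3_CODONS], na.rm = TRUE)))
  invisible(x)
}

#' Codon employment shift between two cohorts
#'
#' Per-codon relative CEC change from a control to a disease cohort,
#' expressed in percent of the control value: 100 * (CEC_d - CEC_c) /
#' |CEC_c|. The absolute-value denominator preserves the direction of the
#' change regardless of the control coefficient's sign. Codons whose control
#' CEC is within `epsilon` of zero (or NA in either cohort) are excluded from
#' the group means and listed. The group summaries average the per-codon
#' changes over the AU3-ending and GC3-ending sense codons.
#'
#' @param control,disease `cohort_cec` objects (or bare 61-entry CEC vectors)
#'   computed on the same gene universe and codon order.
#' @param epsilon Exclusion floor for |control CEC| (default 0.01).
#' @return List of class `employment_shift`: `per_codon` (61-entry percent
#'   changes, NA where excluded), `au3_shift_pct`, `gc3_shift_pct`,
#'   `excluded` (codon names).
#' @export
employment_shift <- function(control, disease, epsilon = 0.01) {
  c_mean <- cec_mean_of(control)
  d_mean <- cec_mean_of(disease)
  stopifnot(identical(names(c_mean), names(d_mean)))
  excluded <- names(c_mean)[is.na(c_mean) | is.na(d_mean) | abs(c_mean) < epsilon]
  rel <- 100 * (d_mean - c_mean) / abs(c_mean)
  rel[names(rel) %in% excluded] <- NA_real_
  au3_ok <- setdiff(AU3_CODONS, excluded)
  gc3_ok <- setdiff(GC3_CODONS, excluded)
  if (length(au3_ok) == 0L) stop("all AU3 codons excluded; AU3 shift undefined")
  if (length(gc3_ok) == 0L) stop("all GC3 codons excluded; GC3 shift undefined")
  structure(list(per_codon = rel,
                 au3_shift_pct = mean(rel[au3_ok]),
                 gc3_shift_pct = mean(rel[gc3_ok]),
                 excluded = excluded,
                 epsilon = epsilon),
            class = "employment_shift")
}

cec_mean_of <- function(x) {
  if (inherits(x, "cohort_cec")) return(x$mean)
  v <- as.numeric(x)
  nm <- names(x)
  if (is.null(nm)) {
    if (length(v) != length(SENSE_CODONS)) stop("expected a 61-entry CEC vector")
    nm <- SENSE_CODONS
  }
  stats::setNames(v, nm)[SENSE_CODONS]
}

#' @export
print.employment_shift <- function(x, ...) {
  cat(sprintf("employment_shift: AU3 %+.1f%%, GC3 %+.1f%% (%d codons excluded)\n",
              x$au3_shift_pct, x$gc3_shift_pct, length(x$excluded)))
  invisible(x)
}

#' CorrCEC: correlation of transcript composition to codon employment
#'
#' For every transcript, correlates its 61-codon composition vector with the
#' control-cohort and disease-cohort CEC vectors. The score is
#' r_disease - r_control: negative scores mark transcripts whose composition
#' matches the codon employment preferred in the control situation, positive
#' scores the disease situation. Swapping the cohorts negates the score
#' exactly. An alternative scalarization — the correlation of the composition
#' with the disease-minus-control CEC difference vector — is available via
#' `method = "difference_vector"`.
#'
#' @inheritParams compute_cec
#' @param control_cec,disease_cec `cohort_cec` objects or 61-entry CEC
#'   vectors.
#' @param method `"difference_of_correlations"` (default) or
#'   `"difference_vector"`.
#' @return Data frame with columns `gene_id`, `r_control`, `r_disease`,
#'   `score`. Genes with fewer than 3 jointly defined codon entries are
#'   dropped with a warning.
#' @export
corrcec <- function(profiles, control_cec, disease_cec, subset = NULL,
                    method = c("difference_of_correlations", "difference_vector")) {
  method <- match.arg(method)
  pct <- profile_pct(profiles)
  genes <- rownames(pct)
  if (!is.null(subset)) genes <- intersect(genes, subset)
  if (length(genes) == 0L) stop("no genes to score")
  c_mean <- cec_mean_of(control_cec)
  d_mean <- cec_mean_of(disease_cec)
  ok <- !is.na(c_mean) & !is.na(d_mean)
  if (sum(ok) < 3L) stop("fewer than 3 jointly defined CEC entries")
  sub <- t(pct[genes, ok, drop = FALSE])
  r_control <- as.numeric(suppressWarnings(stats::cor(sub, c_mean[ok])))
  r_disease <- as.numeric(suppressWarnings(stats::cor(sub, d_mean[ok])))
  bad <- is.na(r_control) | is.na(r_disease)
  if (any(bad)) {
    warning(sum(bad), " gene(s) skipped: constant composition over defined codons")
  }
  score <- if (method == "difference_of_correlations") {
    r_disease - r_control
  } else {
    as.numeric(suppressWarnings(stats::cor(sub, d_mean[ok] - c_mean[ok])))
  }
  data.frame(gene_id = genes, r_control = r_control, r_disease = r_disease,
             score = score)[!bad, ]
}
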
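# Cross-gene codon-codon correlation structure.

#' Codon-codon correlation matrix across genes
#'
#' Correlates, across genes, the within-family synonymous fractions of every
#' pair of codons (see [per_aa_fractions()]). In the default `full` mode the
#' matrix is symmetric with unit diagonal. In `split_half` mode each coding
#' sequence is split in two halves by codon index (trailing stop stripped,
#' extra codon to the first half), fractions are recomputed per half, and the
#' entry (i, j) correlates codon i's fraction in the first halves with codon
#' j's fraction in the second halves — a control showing that compositional
#' coupling is a property of whole genes, not of local repeats.
#'
#' Genes lacking an amino acid are excluded pairwise for pairs involving its
#' codons. Codons with zero variance across genes yield NA rows/columns, never
#' silent zeros.
#'
#' @param x For `mode = "full"`, either a fraction matrix from
#'   [per_aa_fractions()], a `codon_counts` matrix, or a `cds_set`. For
#'   `mode = "split_half"`, a `cds_set` (or named character vector of
#'   sequences), since the halves must be re-counted.
#' @param mode `"full"` or `"split_half"`.
#' @param codons Codon set to include; defaults to the 59 codons of
#'   degenerate families (see [degenerate_codons()]). Pass `sense_codons()`
#'   to include Met/Trp.
#' @param fractions Use within-family fractions (default, TRUE) or raw
#'   61-codon percentages (FALSE).
#' @return Square numeric matrix of Pearson coefficients with codon dimnames
#'   and attribute `mode`.
#' @export
codon_correlation_matrix <- function(x, mode = c("full", "split_half"),
                                     codons = degenerate_codons(),
                                     fractions = TRUE) {
  mode <- match.arg(mode)
  stopifnot(all(codons %in% SENSE_CODONS))
  if (mode == "full") {
    m <- fraction_matrix(x, fractions)
    if (nrow(m) < 3L) stop("need at least 3 genes")
    r <- suppressWarnings(stats::cor(m[, codons, drop = FALSE],
                                     use = "pairwise.complete.obs"))
  } else {
    halves <- split_cds_halves(x)
    ok <- nchar(halves$first) > 0 & nchar(halves$second) > 0
    if (sum(ok) < 3L) stop("need at least 3 genes with non-empty halves")
    m1 <- fraction_matrix(count_codons(halves$first[ok]), fractions)
    m2 <- fraction_matrix(count_codons(halves$second[ok]), fractions)
    r <- suppressWarnings(stats::cor(m1[, codons, drop = FALSE],
                                     m2[, codons, drop = FALSE],
                                     use = "pairwise.complete.obs"))
  }
  attr(r, "mode") <- mode
  r
}

fraction_matrix <- function(x, fractions = TRUE) {
  if (inherits(x, "cds_set")) x <- count_codons(x)
  if (inherits(x, "codon_counts")) {
    if (fractions) per_aa_fractions(x) else composition_profile(x)$pct
  } else {
    as.matrix(x)
  }
}

#' Mean correlation within and between the GC3 and AU3 codon groups
#'
#' Convenience summary of a codon correlation matrix: mean off-diagonal
#' Pearson r within the GC3-ending codons, within the AU3-ending codons, and
#' between the two groups.
#'
#' @param r Matrix from [codon_correlation_matrix()].
#' @return Named numeric vector `c(within_gc3, within_au3, between)`.
#' @export
correlation_group_means <- function(r) {
  gc3 <- intersect(colnames(r), GC3_CODONS)
  au3 <- intersect(colnames(r), AU3_CODONS)
  off_mean <- function(block, drop_diag) {
    if (drop_diag) diag(block) <- NA
    mean(block, na.rm = TRUE)
  }
  c(within_gc3 = off_mean(r[gc3, gc3, drop = FALSE], TRUE),
    within_au3 = off_mean(r[au3, au3, drop = FALSE], TRUE),
    between = off_mean(r[gc3, au3, drop = FALSE], FALSE))
}
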
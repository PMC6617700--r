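# Codon tables for the standard genetic code.
#
# Every 61-entry vector in the package uses the fixed alphabetical order of
# `sense_codons()` (AAA ... TTT, stop codons excluded); file columns and
# matrix dimnames follow the same order.

BASES <- c("A", "C", "G", "T")

# all 64 codons, alphabetical
ALL_CODONS <- sort(apply(expand.grid(BASES, BASES, BASES)[, 3:1], 1L, paste, collapse = ""))

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE[ALL_CODONS]

STOP_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE == "*"]
SENSE_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]

third_base <- function(codons) substr(codons, 3L, 3L)

# GC3 / AU3 dichotomy over sense codons; ATG and TGG end in G and count as GC3
GC3_CODONS <- SENSE_CODONS[third_base(SENSE_CODONS) %in% c("G", "C")]
AU3_CODONS <- SENSE_CODONS[third_base(SENSE_CODONS) %in% c("A", "T")]

# codons of degenerate families (Met and Trp excluded: their per-amino-acid
# fraction is identically 1, hence zero variance across genes)
DEGENERATE_CODONS <- SENSE_CODONS[!SENSE_CODONS %in% c("ATG", "TGG")]

# synonymous families, stop excluded
AA_FAMILIES <- split(SENSE_CODONS, GENETIC_CODE_TABLE[SENSE_CODONS])

#' Codon order used throughout the package
#'
#' All per-codon vectors and matrix margins use the fixed alphabetical order
#' of the 61 sense codons of the standard genetic code (stop codons TAA, TAG,
#' TGA excluded).
#'
#' @return Character vector of 61 sense codons in alphabetical order.
#' @export
sense_codons <- function() SENSE_CODONS

#' @rdname sense_codons
#' @export
stop_codons <- function() STOP_CODONS

#' GC3 and AU3 codon groups
#'
#' A sense codon is GC3 when its third (wobble) base is G or C, and AU3 when
#' it is A or T (U on the mRNA). ATG and TGG end in G and belong to the GC3
#' group.
#'
#' @return Character vector of codons.
#' @export
gc3_codons <- function() GC3_CODONS

#' @rdname gc3_codons
#' @export
au3_codons <- function() AU3_CODONS

#' Codons of degenerate synonymous families
#'
#' The 59 sense codons whose amino acid is encoded by more than one codon.
#' Used as the default codon set of [codon_correlation_matrix()], since the
#' single-codon families (Met, Trp) have per-amino-acid fraction identically 1.
#'
#' @return Character vector of 59 codons.
#' @export
degenerate_codons <- function() DEGENERATE_CODONS

#' Synonymous codon families
#'
#' @return Named list mapping each amino acid (one-letter code) to its sense
#'   codons.
#' @export
codon_families <- function() AA_FAMILIES
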
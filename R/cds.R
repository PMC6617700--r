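# Coding-sequence ingestion and codon-level composition statistics.

#' Read and validate coding sequences from FASTA
#'
#' Reads a multi-record FASTA of coding sequences (CDS), normalizes records
#' (upper case, RNA U converted to T) and validates them. Gene ids are taken
#' as the first whitespace-delimited token of each header; duplicated ids keep
#' the first record with a warning.
#'
#' @param fasta_source Path to a FASTA file.
#' @param policy `"strict"` rejects records whose length is not a multiple of
#'   3 or that contain non-ACGT characters after normalization; `"lenient"`
#'   trims a trailing partial codon and drops codons containing ambiguity
#'   codes.
#' @return An object of class `cds_set`: a list with `sequences` (named
#'   character vector of normalized DNA sequences) and `rejected` (data frame
#'   with columns `gene_id`, `reason`).
#' @export
read_cds <- function(fasta_source, policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  if (!file.exists(fasta_source)) {
    stop("cannot read FASTA file: ", fasta_source)
  }
  recs <- Biostrings::readBStringSet(fasta_source)
  seqs <- as.character(recs)
  ids <- vapply(strsplit(names(recs), "\\s+"), `[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning("duplicate gene ids, keeping first record of: ",
            paste(dup, collapse = ", "))
    keep <- !duplicated(ids)
    seqs <- seqs[keep]
    ids <- ids[keep]
  }
  names(seqs) <- ids
  cds_from_strings(seqs, policy = policy)
}

#' Build a validated `cds_set` from in-memory sequences
#'
#' Same normalization and validation as [read_cds()] but starting from a
#' named character vector (as produced by [generate_cds_set()]).
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @inheritParams read_cds
#' @return A `cds_set`.
#' @export
cds_from_strings <- function(seqs, policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must carry gene ids as names")
  }
  norm <- chartr("u", "t", tolower(seqs))
  norm <- toupper(chartr("t", "t", norm))
  rejected <- data.frame(gene_id = character(0), reason = character(0))
  keep <- rep(TRUE, length(norm))
  for (i in seq_along(norm)) {
    s <- norm[[i]]
    if (nchar(s) == 0L) {
      keep[i] <- FALSE
      rejected <- rbind(rejected,
                        data.frame(gene_id = names(norm)[i], reason = "empty sequence"))
      next
    }
    if (nchar(s) %% 3L != 0L) {
      if (policy == "strict") {
        keep[i] <- FALSE
        rejected <- rbind(rejected,
                          data.frame(gene_id = names(norm)[i],
                                     reason = "length not a multiple of 3"))
        next
      }
      s <- substr(s, 1L, nchar(s) - nchar(s) %% 3L)
    }
    cods <- codon_split(s)
    bad <- grepl("[^ACGT]", cods)
    if (any(bad)) {
      if (policy == "strict") {
        keep[i] <- FALSE
        rejected <- rbind(rejected,
                          data.frame(gene_id = names(norm)[i],
                                     reason = "ambiguity codes present"))
        next
      }
      cods <- cods[!bad]
      if (length(cods) == 0L) {
        keep[i] <- FALSE
        rejected <- rbind(rejected,
                          data.frame(gene_id = names(norm)[i],
                                     reason = "no unambiguous codons"))
        next
      }
      s <- paste(cods, collapse = "")
    }
    norm[[i]] <- s
  }
  sequences <- norm[keep]
  if (length(sequences) == 0L) {
    stop("no valid coding sequences after validation (",
         nrow(rejected), " rejected)")
  }
  structure(list(sequences = sequences, rejected = rejected, policy = policy),
            class = "cds_set")
}

#' @export
print.cds_set <- function(x, ...) {
  cat("cds_set:", length(x$sequences), "sequences")
  if (nrow(x$rejected) > 0) cat(",", nrow(x$rejected), "rejected")
  cat("\n")
  invisible(x)
}

codon_split <- function(s) {
  n <- nchar(s) %/% 3L
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Count codons in coding sequences
#'
#' Tallies non-overlapping frame-0 triplets of every sequence over all 64
#' codons. Totals are conserved: each row sums to the sequence length divided
#' by 3.
#'
#' @param x A `cds_set`, or a named character vector of normalized DNA
#'   sequences whose lengths are multiples of 3.
#' @return Integer matrix (genes x 64 codons, alphabetical codon order) of
#'   class `codon_counts`.
#' @export
count_codons <- function(x) {
  seqs <- if (inherits(x, "cds_set")) x$sequences else x
  if (is.null(names(seqs))) stop("sequences must be named")
  counts <- t(vapply(seqs, function(s) {
    tabulate(factor(codon_split(s), levels = ALL_CODONS), nbins = 64L)
  }, integer(64L)))
  dimnames(counts) <- list(names(seqs), ALL_CODONS)
  class(counts) <- c("codon_counts", class(counts))
  counts
}

n_sense <- function(counts) rowSums(counts[, SENSE_CODONS, drop = FALSE])
n_stop <- function(counts) rowSums(counts[, STOP_CODONS, drop = FALSE])

as_count_matrix <- function(counts) {
  if (is.null(dim(counts))) {
    counts <- matrix(counts, nrow = 1L,
                     dimnames = list("gene", names(counts)))
  }
  if (!all(ALL_CODONS %in% colnames(counts))) {
    full <- matrix(0L, nrow(counts), 64L,
                   dimnames = list(rownames(counts), ALL_CODONS))
    full[, colnames(counts)] <- as.matrix(counts)
    counts <- full
  }
  counts[, ALL_CODONS, drop = FALSE]
}

#' Per-transcript codon composition and wobble-position content
#'
#' For each gene computes the 61-entry sense-codon percentage vector
#' (each entry is 100 * count / number of sense codons) and the GC3/AU3
#' content. By convention the GC3 and AU3 percentages use the total codon
#' count (stop codon included) as denominator while stop codons are excluded
#' from both numerators; this is the unique convention reproducing the
#' published VAMP2 worked values (85/117 = 72.65%, 31/117 = 26.50%). A
#' sense-only denominator is available via `gc3_denominator = "sense"`.
#'
#' @param counts A `codon_counts` matrix (see [count_codons()]), or a single
#'   named count vector.
#' @param gc3_denominator `"all"` (default, stop codons in the denominator) or
#'   `"sense"`.
#' @return Object of class `composition_profile`: list with `pct` (genes x 61
#'   matrix), `gc3_pct`, `au3_pct`, `n_codons`, `n_sense`, `n_stop` (named
#'   vectors), and `gc3_denominator`.
#' @export
composition_profile <- function(counts, gc3_denominator = c("all", "sense")) {
  gc3_denominator <- match.arg(gc3_denominator)
  counts <- as_count_matrix(counts)
  ns <- n_sense(counts)
  nst <- n_stop(counts)
  ntot <- ns + nst
  if (any(ntot < 1L)) stop("empty sequences in count table")
  sense <- counts[, SENSE_CODONS, drop = FALSE]
  pct <- 100 * sense / ifelse(ns > 0, ns, NA_real_)
  if (any(ns == 0L)) {
    warning("genes with no sense codons: 61-codon percentages undefined for ",
            paste(rownames(counts)[ns == 0L], collapse = ", "))
  }
  denom <- if (gc3_denominator == "all") ntot else ns
  gc3 <- 100 * rowSums(sense[, GC3_CODONS, drop = FALSE]) / denom
  au3 <- 100 * rowSums(sense[, AU3_CODONS, drop = FALSE]) / denom
  structure(list(pct = pct,
                 gc3_pct = stats::setNames(gc3, rownames(counts)),
                 au3_pct = stats::setNames(au3, rownames(counts)),
                 n_codons = stats::setNames(ntot, rownames(counts)),
                 n_sense = stats::setNames(ns, rownames(counts)),
                 n_stop = stats::setNames(nst, rownames(counts)),
                 gc3_denominator = gc3_denominator),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("composition_profile:", nrow(x$pct), "genes, gc3 denominator =",
      x$gc3_denominator, "\n")
  invisible(x)
}

#' Within-family synonymous codon fractions
#'
#' For each gene and amino acid present in it, the fraction each synonymous
#' codon contributes to that amino acid's codons (e.g. the proportion of all
#' alanine codons that are GCC). Fractions are undefined (NA) for amino acids
#' absent from a gene; within every present family they sum to 1.
#'
#' @inheritParams composition_profile
#' @return Numeric matrix (genes x 61 sense codons) of fractions with NA for
#'   absent families.
#' @export
per_aa_fractions <- function(counts) {
  counts <- as_count_matrix(counts)
  sense <- counts[, SENSE_CODONS, drop = FALSE]
  frac <- matrix(NA_real_, nrow(sense), ncol(sense), dimnames = dimnames(sense))
  for (fam in AA_FAMILIES) {
    tot <- rowSums(sense[, fam, drop = FALSE])
    frac[, fam] <- sense[, fam, drop = FALSE] / ifelse(tot > 0, tot, NA_real_)
  }
  frac
}

#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of a codon is its observed count divided by the mean count over its
#' synonymous family (stop codons excluded); 1 means unbiased usage, the
#' family size is the maximum. Families with zero total count yield NA,
#' reported as missing rather than zero.
#'
#' @param counts A `codon_counts` matrix (rows are pooled by summation), or a
#'   single named count vector.
#' @return Named numeric vector over the 61 sense codons, with attribute
#'   `family_sizes` (named integer vector over amino acids).
#' @export
rscu <- function(counts) {
  counts <- as_count_matrix(counts)
  pooled <- colSums(counts[, SENSE_CODONS, drop = FALSE])
  out <- stats::setNames(rep(NA_real_, length(SENSE_CODONS)), SENSE_CODONS)
  for (fam in AA_FAMILIES) {
    tot <- sum(pooled[fam])
    if (tot > 0) out[fam] <- pooled[fam] / (tot / length(fam))
  }
  attr(out, "family_sizes") <-
    vapply(AA_FAMILIES, length, integer(1L))
  out
}

# Split each CDS into two halves by codon index. The trailing stop codon (if
# any) is stripped first; for odd sense-codon counts the extra codon goes to
# the first half.
split_cds_halves <- function(cds) {
  seqs <- if (inherits(cds, "cds_set")) cds$sequences else cds
  halves <- lapply(seqs, function(s) {
    cods <- codon_split(s)
    if (length(cods) > 0L && cods[length(cods)] %in% STOP_CODONS) {
      cods <- cods[-length(cods)]
    }
    k <- ceiling(length(cods) / 2)
    list(first = paste(cods[seq_len(k)], collapse = ""),
         second = paste(cods[setdiff(seq_along(cods), seq_len(k))], collapse = ""))
  })
  list(first = stats::setNames(vapply(halves, `[[`, character(1L), "first"), names(seqs)),
       second = stats::setNames(vapply(halves, `[[`, character(1L), "second"), names(seqs)))
}
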
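# GC3-ranked pre-ranked gene-set enrichment with a permutation null.
#
# The ranking statistic is the log2 ratio of a gene's GC3 percentage to the
# mean GC3 percentage over all ranked genes. Enrichment uses the standard
# weighted running-sum (Kolmogorov-Smirnov-like) statistic: positive ES means
# the set concentrates at the GC3-rich top of the list, negative ES at the
# AU3-rich bottom.

#' Rank genes by relative GC3 content
#'
#' Scores every gene as log2(gc3_pct / mean gc3_pct) over the included genes
#' and sorts descending. Genes with gc3_pct <= 0 are excluded with a warning
#' (their log ratio is not finite). Ties are broken lexicographically by gene
#' id so the ranking is deterministic.
#'
#' @param profiles A `composition_profile`, or a named numeric vector of
#'   per-gene GC3 percentages.
#' @return Data frame of class `ranked_genes` with columns `gene_id`, `score`
#'   (sorted descending) and attribute `mean_gc3_pct`.
#' @export
rank_by_gc3 <- function(profiles) {
  gc3 <- if (inherits(profiles, "composition_profile")) profiles$gc3_pct else profiles
  if (is.null(names(gc3))) stop("gc3 values must be named by gene id")
  bad <- !is.finite(gc3) | gc3 <= 0
  if (any(bad)) {
    warning("excluding ", sum(bad), " gene(s) with non-positive GC3: ",
            paste(utils::head(names(gc3)[bad], 5L), collapse = ", "))
    gc3 <- gc3[!bad]
  }
  if (length(gc3) < 2L) stop("need at least 2 genes with positive GC3")
  score <- log2(gc3 / mean(gc3))
  ord <- order(-score, names(gc3))
  out <- data.frame(gene_id = names(gc3)[ord], score = as.numeric(score[ord]))
  attr(out, "mean_gc3_pct") <- mean(gc3)
  class(out) <- c("ranked_genes", "data.frame")
  out
}

# Weighted running-sum enrichment score for hit positions `pos` (sorted or
# not) in a list of n scores (descending). Returns the signed extremum, its
# position, and the running sum.
running_sum_es <- function(scores, pos, weight = 1) {
  n <- length(scores)
  nh <- length(pos)
  w <- abs(scores[pos])^weight
  if (sum(w) == 0) w <- rep(1, nh)   # all-zero scores: unweighted
  inc <- numeric(n)
  inc[pos] <- w / sum(w)
  dec <- rep(1 / (n - nh), n)
  dec[pos] <- 0
  run <- cumsum(inc - dec)
  i <- which.max(abs(run))
  list(es = run[i], arg = i, run = run)
}

# O(k) enrichment score for sorted hit positions: the running sum attains its
# maximum at a hit and its minimum immediately before a hit, so only those 2k
# candidate values need evaluating. Equals running_sum_es()$es up to ties of
# measure zero.
es_at_hits <- function(scores, pos, weight = 1) {
  n <- length(scores)
  k <- length(pos)
  w <- abs(scores[pos])^weight
  tot <- sum(w)
  if (tot == 0) {
    w <- rep(1, k)
    tot <- k
  }
  csum <- cumsum(w) / tot
  miss <- (pos - seq_len(k)) / (n - k)  # misses accumulated before each hit
  top <- csum - miss                    # running value at each hit
  bot <- csum - w / tot - miss          # running value just before each hit
  hi <- max(top)
  lo <- min(bot)
  if (abs(hi) >= abs(lo)) hi else lo
}

#' Pre-ranked gene-set enrichment with a gene-permutation null
#'
#' Computes, per gene set, the weighted running-sum enrichment score (hits
#' increment proportionally to |score|^weight, misses decrement uniformly),
#' a two-sided permutation p-value from a signed gene-label permutation null,
#' a normalized enrichment score (ES divided by the mean |null ES| of the
#' same sign), BH FDR across sets, and the leading-edge genes (set members at
#' or before the running-sum extremum for positive ES, at or after it for
#' negative ES).
#'
#' For small problems (`choose(n, set size)` below `exact_limit`) the null is
#' enumerated exhaustively over all placements of the set, making p-values
#' exact rather than sampled.
#'
#' @param ranked A `ranked_genes` data frame from [rank_by_gc3()] (or any
#'   data frame with `gene_id` and `score` sorted descending).
#' @param sets Named list of character vectors of gene ids (see
#'   [read_gene_sets()]).
#' @param n_perm Number of permutations (default 1000; a warning is issued
#'   below 100).
#' @param weight Hit-weighting exponent (default 1; 0 gives the classic
#'   Kolmogorov-Smirnov form).
#' @param seed Integer seed for the permutation null.
#' @param min_size,max_size Set-size bounds after intersection with the
#'   ranked list; sets outside are skipped with a message.
#' @param exact_limit Enumerate the null exhaustively when the number of
#'   placements is at most this value (default 5e5).
#' @return Data frame of class `enrichment_result`: one row per analyzed set
#'   with columns `set_id`, `size`, `es`, `nes`, `p_perm`, `fdr_bh`,
#'   `direction` ("gc3_enriched" / "au3_enriched"), `leading_edge`
#'   (list column).
#' @export
preranked_enrichment <- function(ranked, sets, n_perm = 1000, weight = 1,
                                 seed = 1, min_size = 5, max_size = 500,
                                 exact_limit = 5e5) {
  stopifnot(is.data.frame(ranked), all(c("gene_id", "score") %in% names(ranked)))
  if (n_perm < 100) warning("n_perm < 100: permutation p-values are unstable")
  scores <- ranked$score
  genes <- ranked$gene_id
  n <- length(genes)
  rows <- list()
  set.seed(as.integer(seed %% .Machine$integer.max))
  for (sid in names(sets)) {
    members <- unique(sets[[sid]])
    pos <- sort(match(members, genes))
    pos <- pos[!is.na(pos)]
    k <- length(pos)
    if (k < min_size || k > max_size) {
      message("skipping set '", sid, "': size ", k, " outside [",
              min_size, ", ", max_size, "]")
      next
    }
    if (k >= n) stop("set '", sid, "' covers the entire ranked list")
    obs <- running_sum_es(scores, pos, weight)
    le <- leading_edge_genes(genes, pos, obs)
    if (choose(n, k) <= exact_limit) {
      placements <- utils::combn(n, k)
      null_es <- apply(placements, 2L, function(p) es_at_hits(scores, p, weight))
      p_perm <- mean(abs(null_es) >= abs(obs$es) - 1e-12)
    } else {
      null_es <- vapply(seq_len(n_perm), function(i) {
        es_at_hits(scores, sort(sample.int(n, k)), weight)
      }, numeric(1L))
      p_perm <- (1 + sum(abs(null_es) >= abs(obs$es) - 1e-12)) / (n_perm + 1)
    }
    same_sign <- null_es[sign(null_es) == sign(obs$es)]
    nes <- if (length(same_sign) > 0) obs$es / mean(abs(same_sign)) else NA_real_
    rows[[sid]] <- data.frame(set_id = sid, size = k, es = obs$es, nes = nes,
                              p_perm = p_perm)
    rows[[sid]]$leading_edge <- list(le)
  }
  if (length(rows) == 0L) stop("no analyzable sets")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr_bh <- bh_fdr(out$p_perm)
  out$direction <- ifelse(out$es >= 0, "gc3_enriched", "au3_enriched")
  out <- out[, c("set_id", "size", "es", "nes", "p_perm", "fdr_bh",
                 "direction", "leading_edge")]
  class(out) <- c("enrichment_result", "data.frame")
  out
}

leading_edge_genes <- function(genes, pos, obs) {
  if (obs$es >= 0) genes[pos[pos <= obs$arg]] else genes[pos[pos >= obs$arg]]
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH adjustment of a vector of p-values (delegates to
#' [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

#' Derive the AU3-rich (GP1) and GC3-rich (GP2) gene groups
#'
#' GP1 is the union of leading-edge genes of significantly AU3-enriched sets
#' (FDR below the cut, negative ES); GP2 the same for positive ES. Genes
#' falling in both unions are dropped from both with a warning.
#'
#' @param results An `enrichment_result` from [preranked_enrichment()].
#' @param fdr_cut FDR threshold (default 0.01).
#' @param use_leading_edge Use leading-edge genes (default) or full set
#'   membership.
#' @param sets Required when `use_leading_edge = FALSE`: the original set
#'   list.
#' @return List with character vectors `gp1` and `gp2`.
#' @export
derive_groups <- function(results, fdr_cut = 0.01, use_leading_edge = TRUE,
                          sets = NULL) {
  sig <- results[!is.na(results$fdr_bh) & results$fdr_bh < fdr_cut, ]
  member_genes <- function(rows) {
    if (nrow(rows) == 0L) return(character(0))
    if (use_leading_edge) {
      unique(unlist(rows$leading_edge))
    } else {
      if (is.null(sets)) stop("sets required when use_leading_edge = FALSE")
      unique(unlist(sets[rows$set_id]))
    }
  }
  gp1 <- member_genes(sig[sig$es < 0, ])
  gp2 <- member_genes(sig[sig$es >= 0, ])
  shared <- intersect(gp1, gp2)
  if (length(shared) > 0L) {
    warning(length(shared), " gene(s) in both groups, excluded from both")
    gp1 <- setdiff(gp1, shared)
    gp2 <- setdiff(gp2, shared)
  }
  if (length(gp1) == 0L && length(gp2) == 0L) {
    message("no significant sets at FDR < ", fdr_cut, "; both groups empty")
  }
  list(gp1 = gp1, gp2 = gp2)
}

#' GC3-perturbation robustness of the enrichment analysis
#'
#' Repeats the ranking + enrichment after jittering every gene's GC3
#' percentage by independent additive uniform noise of magnitude +/- delta
#' percentage points (clipped to (0, 100]), and counts the gene sets that
#' remain significant (FDR below `fdr_cut`) in at least `min_hits` of the
#' `n_reps` replicates, per delta. A multiplicative jitter mode
#' (gene's GC3 scaled by 1 +/- delta/100) is available.
#'
#' @param gc3 Named numeric vector of per-gene GC3 percentages (or a
#'   `composition_profile`).
#' @param sets Named list of gene sets.
#' @param deltas Numeric vector of non-negative jitter magnitudes in
#'   percentage points (default `c(0, 5, 10, 15)`).
#' @param n_reps Replicates per delta (default 5).
#' @param fdr_cut Significance threshold (default 0.01).
#' @param min_hits Minimum significant replicates for a set to count as
#'   surviving (default 5).
#' @param n_perm,weight Passed to [preranked_enrichment()].
#' @param mode `"additive"` (default) or `"multiplicative"`.
#' @param seed Master seed; replicate seeds are derived deterministically.
#' @return Data frame with columns `delta` and `surviving_sets`.
#' @export
perturbation_robustness <- function(gc3, sets, deltas = c(0, 5, 10, 15),
                                    n_reps = 5, fdr_cut = 0.01, min_hits = 5,
                                    n_perm = 500, weight = 1,
                                    mode = c("additive", "multiplicative"),
                                    seed = 1) {
  mode <- match.arg(mode)
  if (any(deltas < 0)) stop("delta must be non-negative")
  if (n_reps < min_hits) stop("n_reps must be at least min_hits")
  if (inherits(gc3, "composition_profile")) gc3 <- gc3$gc3_pct
  out <- lapply(deltas, function(delta) {
    sig_count <- matrix(FALSE, nrow = length(sets), ncol = n_reps,
                        dimnames = list(names(sets), NULL))
    for (rep_i in seq_len(n_reps)) {
      rep_seed <- (seed + 7919 * rep_i + 104729 * round(delta)) %% .Machine$integer.max
      set.seed(as.integer(rep_seed))
      jitter <- stats::runif(length(gc3), -delta, delta)
      g <- if (mode == "additive") gc3 + jitter else gc3 * (1 + jitter / 100)
      g <- pmin(pmax(g, 1e-6), 100)
      names(g) <- names(gc3)
      ranked <- suppressWarnings(rank_by_gc3(g))
      res <- preranked_enrichment(ranked, sets, n_perm = n_perm,
                                  weight = weight, seed = rep_seed)
      sig <- res$set_id[!is.na(res$fdr_bh) & res$fdr_bh < fdr_cut]
      sig_count[sig, rep_i] <- TRUE
    }
    data.frame(delta = delta,
               surviving_sets = sum(rowSums(sig_count) >= min_hits))
  })
  do.call(rbind, out)
}
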
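# Independent brute-force oracles, deliberately written without reusing any
# package internals.

# two-pass Pearson correlation
pearson_naive <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# step-up Benjamini-Hochberg, literal textbook form
bh_stepup <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in seq(m, 1)) {
    val <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- val
    prev <- val
  }
  q
}

# full running-sum enrichment score by explicit walk over every position
es_naive <- function(scores, hit_positions, weight = 1) {
  n <- length(scores)
  hits <- logical(n)
  hits[hit_positions] <- TRUE
  w <- abs(scores[hit_positions])^weight
  wsum <- sum(w)
  running <- 0
  best <- 0
  wi <- 0
  for (i in seq_len(n)) {
    if (hits[i]) {
      wi <- wi + 1
      running <- running + abs(scores[i])^weight / wsum
    } else {
      running <- running - 1 / (n - length(hit_positions))
    }
    if (abs(running) > abs(best)) best <- running
  }
  best
}

# exhaustive enumeration of the gene-permutation ES null
es_null_exhaustive <- function(scores, k, weight = 1) {
  placements <- utils::combn(length(scores), k)
  apply(placements, 2L, function(p) es_naive(scores, p, weight))
}

# FWHM by exhaustive scan over bins: global max, then walk out to the first
# half-max crossings and interpolate linearly
fwhm_scan <- function(mids, counts) {
  peak <- which.max(counts)
  half <- counts[peak] / 2
  left <- right <- NA_real_
  i <- peak
  while (i > 1) {
    if (counts[i] >= half && counts[i - 1] < half) {
      left <- mids[i - 1] + (half - counts[i - 1]) / (counts[i] - counts[i - 1]) *
        (mids[i] - mids[i - 1])
      break
    }
    i <- i - 1
  }
  i <- peak
  while (i < length(counts)) {
    if (counts[i] >= half && counts[i + 1] < half) {
      right <- mids[i] + (counts[i] - half) / (counts[i] - counts[i + 1]) *
        (mids[i + 1] - mids[i])
      break
    }
    i <- i + 1
  }
  right - left
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
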
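# Summary of the per-gene GC3 distribution: histogram, median, FWHM.

#' Summarize a per-gene GC3 distribution
#'
#' Builds a histogram of per-gene GC3 percentages over \[0, 100\] and reports
#' median, min, max and the full width at half maximum (FWHM) of the
#' histogram. The FWHM is measured around the global mode by linear
#' interpolation of the two half-maximum crossings of the (optionally
#' smoothed) bin counts; it is the spread statistic used to compare the
#' width of GC3 distributions across gene sets or organisms.
#'
#' @param gc3_values Numeric vector of per-gene GC3 percentages, or a
#'   `composition_profile` (its `gc3_pct` is used).
#' @param bin_width Histogram bin width in percentage points (default 1).
#' @param smooth Apply a centered moving average of window 3 to the bin
#'   counts before the half-maximum search (default TRUE).
#' @return List of class `gc3_summary`: `median`, `min`, `max`, `fwhm`
#'   (NA when undefined, e.g. all values identical), `breaks`, `counts`,
#'   `mids`, `n`.
#' @export
gc3_distribution_summary <- function(gc3_values, bin_width = 1, smooth = TRUE) {
  if (inherits(gc3_values, "composition_profile")) {
    gc3_values <- gc3_values$gc3_pct
  }
  gc3_values <- gc3_values[is.finite(gc3_values)]
  if (length(gc3_values) < 2L) stop("need at least two finite GC3 values")
  if (bin_width <= 0) stop("bin_width must be positive")
  breaks <- seq(0, 100 + bin_width, by = bin_width)
  breaks <- breaks[breaks <= 100 + bin_width / 2]
  if (breaks[length(breaks)] < 100) breaks <- c(breaks, 100)
  h <- graphics::hist(pmin(pmax(gc3_values, 0), 100), breaks = breaks,
                      plot = FALSE)
  counts <- h$counts
  work <- if (smooth && length(counts) >= 3L) {
    as.numeric(stats::filter(counts, rep(1 / 3, 3), sides = 2))
  } else {
    as.numeric(counts)
  }
  work[is.na(work)] <- counts[is.na(work)]
  # fewer than two occupied raw bins: no finite width regardless of smoothing
  fwhm <- if (sum(counts > 0) < 2L) NA_real_ else fwhm_from_histogram(h$mids, work)
  structure(list(median = stats::median(gc3_values),
                 min = min(gc3_values), max = max(gc3_values),
                 fwhm = fwhm, breaks = h$breaks, counts = counts,
                 mids = h$mids, n = length(gc3_values)),
            class = "gc3_summary")
}

# Half-maximum crossing search around the global mode, with linear
# interpolation between bin centers. Returns NA when a finite width is not
# defined (fewer than two occupied bins, or the half-max level is never
# crossed on either side).
fwhm_from_histogram <- function(mids, counts) {
  if (sum(counts > 0) < 2L) return(NA_real_)
  peak <- which.max(counts)
  half <- counts[peak] / 2
  left <- NA_real_
  if (peak > 1L) {
    for (i in seq.int(peak, 2L, by = -1L)) {
      if (counts[i - 1L] < half && counts[i] >= half) {
        left <- mids[i - 1L] +
          (half - counts[i - 1L]) / (counts[i] - counts[i - 1L]) * (mids[i] - mids[i - 1L])
        break
      }
    }
  }
  right <- NA_real_
  if (peak < length(counts)) {
    for (i in seq.int(peak, length(counts) - 1L)) {
      if (counts[i + 1L] < half && counts[i] >= half) {
        right <- mids[i] +
          (counts[i] - half) / (counts[i] - counts[i + 1L]) * (mids[i + 1L] - mids[i])
        break
      }
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  right - left
}

#' @export
print.gc3_summary <- function(x, ...) {
  cat(sprintf("gc3_summary: n = %d, median = %.2f%%, range = [%.2f, %.2f], fwhm = %s\n",
              x$n, x$median, x$min, x$max,
              if (is.na(x$fwhm)) "undefined" else sprintf("%.2f", x$fwhm)))
  invisible(x)
}
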
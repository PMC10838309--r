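# Binding-track normalization, imaging-window calls, and the small summary
# statistics used when validating probe sets (two-sided Fisher exact test
# on foci-count tables, rounded percentages).

#' Min-max normalize a per-bin binding track to 0..255
#'
#' @param raw Numeric vector of per-bin summed duplex scores.
#' @return Integer vector: `round(255 * (raw - min) / (max - min))`
#'   (half-up); all-equal input maps to all zeros.
#' @export
normalize_track <- function(raw) {
  stopifnot(length(raw) >= 1L)
  rng <- range(raw)
  if (rng[[1L]] == rng[[2L]]) return(integer(length(raw)))
  as.integer(floor(255 * (raw - rng[[1L]]) / (rng[[2L]] - rng[[1L]]) + 0.5))
}

#' Imaging target window from a binding track
#'
#' The smallest interval spanning all target-overlapping bins whose raw
#' binding sum exceeds `align_thresh`.
#'
#' @param bins Interval data.frame of track bins.
#' @param raw Numeric vector of per-bin raw binding sums (same order).
#' @param target Single-row target interval.
#' @param align_thresh Raw-score threshold (strictly exceeded to qualify).
#' @return Single-row interval data.frame.
#' @export
imaging_window <- function(bins, raw, target, align_thresh) {
  stopifnot(nrow(bins) == length(raw), nrow(target) == 1L)
  qual <- raw > align_thresh &
    bins$scaffold == target$scaffold &
    bins$start < target$end & bins$end > target$start
  if (!any(qual)) {
    stop("no target-overlapping bin exceeds align_thresh = ", align_thresh)
  }
  bed_intervals(target$scaffold, min(bins$start[qual]), max(bins$end[qual]),
                "imaging_window")
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric two-sided p-value: the sum of probabilities of all
#' tables with the observed margins whose probability does not exceed the
#' observed table's.
#'
#' @param a,b,c,d Counts, row-wise: `(a b / c d)`.
#' @return The p-value; any zero margin returns 1 (no association
#'   assessable), with a warning.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- matrix(c(a, b, c, d), nrow = 2L, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("degenerate 2x2 table (zero margin); returning p = 1")
    return(1)
  }
  stats::fisher.test(m)$p.value
}

#' Rounded percentage of a count over a total
#'
#' @param count,total Non-negative counts, `total > 0`.
#' @param digits Decimal places (half-up rounding).
#' @return `100 * count / total`, rounded.
#' @export
percent_of <- function(count, total, digits = 1L) {
  stopifnot(total > 0)
  scale <- 10^digits
  floor(100 * count / total * scale + 0.5) / scale
}
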
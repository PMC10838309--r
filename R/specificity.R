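# Per-probe on/off-target binding profiles over genome bins.
#
# Each alignment hit carries a duplex probability; On_T sums the scores of
# hits overlapping the target interval by >= 1 bp, Off_T the rest, and
# binding_prop = On_T / (On_T + Off_T). Scores are also aggregated over a
# fixed tiling of the genome into bins; a hit straddling two bins is
# assigned to the bin containing its midpoint, so the bin aggregates
# conserve On_T + Off_T exactly.

#' Tile scaffolds into fixed-size bins
#'
#' @param lengths Named integer vector scaffold -> length (bp).
#' @param bin_size Bin size in bp; the final bin of each scaffold is
#'   truncated at the scaffold end.
#' @return Interval data.frame tiling each scaffold exactly.
#' @export
make_windows <- function(lengths, bin_size) {
  stopifnot(bin_size >= 1L)
  res <- lapply(names(lengths), function(nm) {
    L <- lengths[[nm]]
    starts <- seq.int(0L, L - 1L, by = bin_size)
    data.frame(scaffold = nm, start = as.integer(starts),
               end = as.integer(pmin(starts + bin_size, L)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Build a per-probe specificity profile
#'
#' @param probe_id Identifier carried into the profile.
#' @param hits Hit data.frame from [align_probe()].
#' @param pdups Numeric vector of duplex probabilities, one per hit row.
#' @param target Single-row target interval; a hit is on-target iff it
#'   overlaps the target by at least 1 bp.
#' @param bins Bin data.frame from [make_windows()].
#' @return Object of class `specificity_profile`: list with `probe_id`,
#'   `on_t`, `off_t`, `binding_prop` (`NA` and `valid = FALSE` when total
#'   predicted binding is zero), and `bin_aggregates` (the `bins` with a
#'   `pdups_sum` column).
#' @export
profile_probe <- function(probe_id, hits, pdups, target, bins) {
  stopifnot(nrow(hits) == length(pdups), nrow(target) == 1L)
  on <- hits$scaffold == target$scaffold &
    hits$start < target$end & hits$end > target$start
  on_t <- sum(pdups[on])
  off_t <- sum(pdups[!on])
  total <- on_t + off_t
  agg <- bins
  agg$pdups_sum <- 0
  if (nrow(hits) > 0L) {
    mid <- (hits$start + hits$end) %/% 2L
    for (i in seq_len(nrow(hits))) {
      j <- which(agg$scaffold == hits$scaffold[[i]] &
                   agg$start <= mid[[i]] & mid[[i]] < agg$end)
      if (length(j) == 1L) agg$pdups_sum[[j]] <- agg$pdups_sum[[j]] + pdups[[i]]
    }
  }
  structure(
    list(probe_id = probe_id, on_t = on_t, off_t = off_t,
         binding_prop = if (total > 0) on_t / total else NA_real_,
         valid = total > 0, bin_aggregates = agg),
    class = "specificity_profile"
  )
}

#' @export
print.specificity_profile <- function(x, ...) {
  cat(sprintf("specificity_profile %s: on_t=%.3f off_t=%.3f binding_prop=%s\n",
              x$probe_id, x$on_t, x$off_t,
              if (x$valid) sprintf("%.4f", x$binding_prop) else "NA (invalid)"))
  invisible(x)
}

#' Off-target bin cull
#'
#' @param profile A `specificity_profile`.
#' @param target Single-row target interval.
#' @param off_bin_thresh Maximum allowed aggregate duplex score in any bin
#'   not overlapping the target.
#' @return `TRUE` (pass) or `FALSE` (fail: some non-target bin exceeds the
#'   threshold).
#' @export
off_bin_cull <- function(profile, target, off_bin_thresh) {
  stopifnot(inherits(profile, "specificity_profile"), off_bin_thresh >= 0)
  agg <- profile$bin_aggregates
  off <- !(agg$scaffold == target$scaffold &
             agg$start < target$end & agg$end > target$start)
  !any(agg$pdups_sum[off] > off_bin_thresh)
}
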
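# De novo repeat-interval discovery from per-position k-mer counts.
#
# A position is flagged iff its genome-wide k-mer count exceeds the count
# threshold T (strict inequality). A sliding window of W positions (step 1)
# is repeat-positive iff the fraction of flagged positions in it is >= the
# composition score C. Overlapping positive windows are merged, and each
# merged run is trimmed to the span of flagged positions it contains before
# the k-1 bp extension that covers the final k-mer's footprint: reporting
# raw window unions would pad every array by up to W*(1-C) bp of background
# on each side, which is noise rather than repeat. An alternative
# composition rule (window mean count >= C) is selectable via
# `composition_mode = "mean"`.

#' Discover repetitive intervals along one scaffold
#'
#' @param counts Integer vector of per-position genome-wide k-mer counts for
#'   the scaffold (from [position_counts()]); position `i` of the vector is
#'   0-based genomic offset `i - 1`.
#' @param scaffold Scaffold name for the emitted intervals.
#' @param window Sliding window size W, in positions.
#' @param threshold Count threshold T; a position is flagged iff count > T.
#' @param composition Composition score C in `[0, 1]`.
#' @param file_start 0-based offset at which scanning begins.
#' @param k k-mer length used to build `counts`; interval ends are extended
#'   by `k - 1` bp.
#' @param composition_mode `"flagged"` (default): window positive iff
#'   fraction of flagged positions >= C. `"mean"`: window positive iff mean
#'   count / threshold-normalized score >= C is replaced by mean(count) >= C
#'   (raw mean rule).
#' @return Interval data.frame with columns `scaffold`, `start`, `end`,
#'   `composition` (fraction of flagged positions in the interval at
#'   detection time); sorted, non-overlapping.
#' @export
discover_repeats <- function(counts, scaffold, window, threshold, composition,
                             file_start = 0L, k = 18L,
                             composition_mode = c("flagged", "mean")) {
  composition_mode <- match.arg(composition_mode)
  if (window < 1L) stop("window must be >= 1")
  if (composition < 0 || composition > 1) {
    stop("composition must be in [0, 1], got ", composition)
  }
  if (file_start < 0L) stop("file_start must be >= 0")
  empty <- data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), composition = numeric(0),
                      stringsAsFactors = FALSE)
  if (file_start > 0L) {
    if (file_start >= length(counts)) return(empty)
    counts <- counts[-seq_len(file_start)]
  }
  n <- length(counts)
  if (window > n) return(empty)

  flagged <- counts > threshold
  score_src <- if (composition_mode == "flagged") as.numeric(flagged)
               else as.numeric(counts)
  # rolling mean over W via cumulative sums; window starts 1..n-W+1
  cs <- c(0, cumsum(score_src))
  wmean <- (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
  positive <- wmean >= composition & wmean > 0
  if (!any(positive)) return(empty)

  # merge overlapping positive windows [s, s+W) into maximal runs
  starts <- which(positive)           # 1-based window starts
  runs <- list()
  run_s <- starts[[1L]]
  run_e <- starts[[1L]] + window      # exclusive, 1-based position index
  for (s in starts[-1L]) {
    if (s <= run_e) {
      run_e <- s + window
    } else {
      runs[[length(runs) + 1L]] <- c(run_s, run_e)
      run_s <- s
      run_e <- s + window
    }
  }
  runs[[length(runs) + 1L]] <- c(run_s, run_e)

  out <- lapply(runs, function(r) {
    lo <- r[[1L]]
    hi <- min(r[[2L]] - 1L, n)        # inclusive
    fl <- which(flagged[lo:hi])
    if (length(fl) > 0L) {            # trim to flagged span
      lo2 <- lo + fl[[1L]] - 1L
      hi2 <- lo + fl[[length(fl)]] - 1L
    } else {                          # C = 0 style windows with no flags
      lo2 <- lo; hi2 <- hi
    }
    comp <- mean(flagged[lo2:hi2])
    # convert to 0-based bp: position index i (1-based) covers bp i-1
    c(start = file_start + lo2 - 1L,
      end = file_start + hi2 - 1L + k,   # + (k-1) footprint, half-open
      comp = comp)
  })
  m <- do.call(rbind, out)
  data.frame(scaffold = scaffold,
             start = as.integer(unname(m[, "start"])),
             end = as.integer(unname(m[, "end"])),
             composition = unname(round(m[, "comp"], 4L)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Discover repetitive intervals across a whole assembly
#'
#' Runs [position_counts()] + [discover_repeats()] per scaffold.
#'
#' @param assembly A [genome_assembly()].
#' @param table A `kmer_count_table` built from the assembly.
#' @inheritParams discover_repeats
#' @return Combined interval data.frame across scaffolds.
#' @export
discover_repeats_genome <- function(assembly, table, window, threshold,
                                    composition, file_start = 0L,
                                    composition_mode = c("flagged", "mean")) {
  composition_mode <- match.arg(composition_mode)
  res <- lapply(names(assembly$scaffolds), function(nm) {
    pc <- position_counts(table, assembly$scaffolds[[nm]])
    discover_repeats(pc, nm, window, threshold, composition,
                     file_start = file_start, k = table$k,
                     composition_mode = composition_mode)
  })
  do.call(rbind, res)
}

#' Jaccard overlap of two intervals on the same scaffold
#'
#' @param a,b Single-row interval data.frames.
#' @return Intersection length over union length (0 when scaffolds differ).
#' @export
interval_jaccard <- function(a, b) {
  if (a$scaffold != b$scaffold) return(0)
  inter <- max(0L, min(a$end, b$end) - max(a$start, b$start))
  uni <- (a$end - a$start) + (b$end - b$start) - inter
  inter / uni
}
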
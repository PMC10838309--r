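# Candidate oligo mining from repeat-interval sequence.
#
# Greedy left-to-right scan: a window grows from min_length until its
# formamide-adjusted Tm reaches min_temp (or max_length / the interval end /
# an N stops it); the window is emitted iff length, Tm and GC all fall in
# their bounds, and the scan then resumes past it, so emitted probes never
# overlap. Probes are mined from the forward strand only; the Tm used for
# windowing is the 50%-formamide-adjusted value, matching a 2xSSC / 50%
# formamide hybridization recipe.

#' Mine candidate probes from one target interval
#'
#' @param interval Single-row interval data.frame (the target).
#' @param assembly A [genome_assembly()].
#' @param min_length,max_length Probe length bounds, nt.
#' @param min_temp,max_temp Formamide-adjusted Tm bounds, degC.
#' @param min_gc,max_gc GC bounds, percent.
#' @param sodium_molar Salt for the Tm, mol/L.
#' @param formamide_percent Formamide for the Tm, % v/v.
#' @return Data.frame of candidates in genomic order: `scaffold`, `start`,
#'   `end`, `sequence`, `tm`, `gc_percent`, `length`, `target_id`.
#' @export
mine_candidates <- function(interval, assembly,
                            min_length = 25L, max_length = 50L,
                            min_temp = 42, max_temp = 52,
                            min_gc = 20, max_gc = 80,
                            sodium_molar = 0.39, formamide_percent = 50) {
  stopifnot(nrow(interval) == 1L, min_length >= 2L,
            min_length <= max_length, min_temp <= max_temp, min_gc <= max_gc)
  validate_intervals(interval, assembly)
  seq <- assembly_slice(assembly, interval$scaffold, interval$start,
                        interval$end)
  target_id <- if (!is.null(interval$name) && !is.na(interval$name))
    interval$name else
    sprintf("%s:%d-%d", interval$scaffold, interval$start, interval$end)
  n <- nchar(seq)
  out <- list()
  pos <- 1L  # 1-based within interval
  while (pos + min_length - 1L <= n) {
    win <- substr(seq, pos, pos + min_length - 1L)
    n_at <- regexpr("N", win, fixed = TRUE)
    if (n_at > 0L) {  # skip past the first N in the window
      pos <- pos + n_at
      next
    }
    len <- min_length
    tm <- melting_temperature(win, sodium_molar, formamide_percent)
    while (tm < min_temp && len < max_length && pos + len <= n) {
      nxt <- substr(seq, pos + len, pos + len)
      if (nxt == "N") break
      len <- len + 1L
      win <- substr(seq, pos, pos + len - 1L)
      tm <- melting_temperature(win, sodium_molar, formamide_percent)
    }
    gc <- gc_percent(win)
    if (tm >= min_temp && tm <= max_temp && gc >= min_gc && gc <= max_gc) {
      out[[length(out) + 1L]] <- data.frame(
        scaffold = interval$scaffold,
        start = interval$start + pos - 1L,
        end = interval$start + pos + len - 1L,
        sequence = win, tm = tm, gc_percent = gc, length = len,
        target_id = target_id, stringsAsFactors = FALSE
      )
      pos <- pos + len  # non-overlapping: advance past the emitted probe
    } else {
      pos <- pos + 1L
    }
  }
  if (length(out) == 0L) {
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), sequence = character(0),
                      tm = numeric(0), gc_percent = numeric(0),
                      length = integer(0), target_id = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Remove exact duplicate probe sequences
#'
#' Keeps the first occurrence of each sequence; survivor order preserved.
#'
#' @param candidates Candidate data.frame from [mine_candidates()].
#' @return The deduplicated data.frame.
#' @export
deduplicate <- function(candidates) {
  if (nrow(candidates) == 0L) return(candidates)
  out <- candidates[!duplicated(candidates$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}
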
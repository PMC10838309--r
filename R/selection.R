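# Greedy probe selection over the rank-ordered candidate stream.
#
# Candidates are processed strictly in rank order; each is aligned
# genome-wide, every hit is scored with the two-state duplex model, and the
# resulting profile must clear four gates: per-probe on-target sum, binding
# proportion, the off-target bin cull, and non-redundancy with every
# already-accepted probe (predicted pairwise duplex probability at most
# max_pdups_binding, evaluated by globally aligning the candidate with each
# accepted probe sequence in the hybridization frame). The loop stops when
# the accepted set's aggregate on-target sum reaches target_sum, when
# max_probe_return probes are accepted, or when candidates run out.

#' Selection criteria bundle
#'
#' @param target_sum Required aggregate on-target duplex sum across the
#'   accepted set.
#' @param min_on_target Per-probe on-target sum floor.
#' @param max_probe_return Cap on accepted probes.
#' @param min_binding_prop Per-probe binding-proportion floor.
#' @param max_pdups_binding Maximum allowed predicted duplex probability
#'   between a candidate and any accepted probe.
#' @param off_bin_thresh Off-target bin cull threshold (see
#'   [off_bin_cull()]).
#' @return A list of class `selection_criteria`.
#' @export
selection_criteria <- function(target_sum = 25, min_on_target = 1,
                               max_probe_return = 20L,
                               min_binding_prop = 0.9,
                               max_pdups_binding = 0.5,
                               off_bin_thresh = 10) {
  stopifnot(target_sum >= 0, min_on_target >= 0, max_probe_return >= 1L,
            min_binding_prop >= 0, min_binding_prop <= 1,
            max_pdups_binding >= 0, off_bin_thresh >= 0)
  structure(list(target_sum = target_sum, min_on_target = min_on_target,
                 max_probe_return = as.integer(max_probe_return),
                 min_binding_prop = min_binding_prop,
                 max_pdups_binding = max_pdups_binding,
                 off_bin_thresh = off_bin_thresh),
            class = "selection_criteria")
}

# Predicted duplex probability between two probe sequences: global
# alignment in the hybridization frame (identical sequences pair
# perfectly), then the two-state model on the aligned rows.
probe_pair_pdups <- function(a, b, model) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = substitution_matrix(),
    gapOpening = ALN_GAP_OPEN, gapExtension = ALN_GAP_EXT)
  duplex_probability(as.character(Biostrings::alignedPattern(pa)),
                     as.character(Biostrings::alignedSubject(pa)), model)
}

#' Select final probes for one target
#'
#' @param ranked Rank-ordered candidate data.frame (descending `nr`; the
#'   stream is consumed in row order).
#' @param assembly A [genome_assembly()].
#' @param target Single-row target interval.
#' @param criteria A [selection_criteria()].
#' @param model A [thermo_model()].
#' @param bins Bin data.frame from [make_windows()]; defaults to 1-kb bins
#'   over the assembly.
#' @param seed_length,max_alignments Aligner parameters.
#' @param index Optional precomputed [seed_index()].
#' @return Object of class `probe_set`: list with `accepted` (candidate
#'   rows with `on_t`, `off_t`, `binding_prop` appended), `aggregate_on_t`,
#'   `aggregate_off_t`, `target`, `termination_reason` (one of
#'   `target_sum_met`, `max_probes`, `exhausted`), and `log` (one row per
#'   processed candidate: accept/reject and the failing gate).
#' @export
select_probes <- function(ranked, assembly, target, criteria, model,
                          bins = NULL, seed_length = 15L,
                          max_alignments = 500000L, index = NULL) {
  stopifnot(inherits(criteria, "selection_criteria"),
            inherits(model, "thermo_model"), nrow(target) == 1L)
  if (nrow(ranked) == 0L) stop("candidate stream is empty")
  if (is.null(bins)) bins <- make_windows(assembly$lengths, 1000L)
  if (is.null(index)) index <- seed_index(assembly, seed_length)

  accepted <- list()
  profiles <- list()
  agg_on <- 0
  agg_off <- 0
  reason <- "exhausted"
  log_rows <- list()
  note <- function(i, decision, why = "") {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      rank = i, sequence = ranked$sequence[[i]], decision = decision,
      reason = why, stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(ranked))) {
    cand <- ranked[i, , drop = FALSE]
    hits <- align_probe(cand$sequence, assembly, seed_length,
                        max_alignments, index = index)
    if (nrow(hits) == 0L) { note(i, "reject", "no_alignments"); next }
    pd <- vapply(seq_len(nrow(hits)), function(j)
      duplex_probability(hits$probe_row[[j]], hits$target_row[[j]], model),
      numeric(1))
    prof <- profile_probe(cand$sequence, hits, pd, target, bins)
    if (!prof$valid) { note(i, "reject", "zero_predicted_binding"); next }
    if (prof$on_t < criteria$min_on_target) {
      note(i, "reject", "min_on_target"); next
    }
    if (prof$binding_prop < criteria$min_binding_prop) {
      note(i, "reject", "min_binding_prop"); next
    }
    if (!off_bin_cull(prof, target, criteria$off_bin_thresh)) {
      note(i, "reject", "off_bin_thresh"); next
    }
    redundant <- FALSE
    for (acc in accepted) {
      if (probe_pair_pdups(cand$sequence, acc$sequence, model) >
          criteria$max_pdups_binding) { redundant <- TRUE; break }
    }
    if (redundant) { note(i, "reject", "max_pdups_binding"); next }

    cand$on_t <- prof$on_t
    cand$off_t <- prof$off_t
    cand$binding_prop <- prof$binding_prop
    accepted[[length(accepted) + 1L]] <- cand
    profiles[[length(profiles) + 1L]] <- prof
    agg_on <- agg_on + prof$on_t
    agg_off <- agg_off + prof$off_t
    note(i, "accept")
    if (agg_on >= criteria$target_sum) { reason <- "target_sum_met"; break }
    if (length(accepted) >= criteria$max_probe_return) {
      reason <- "max_probes"; break
    }
  }

  acc_df <- if (length(accepted) > 0L) do.call(rbind, accepted) else NULL
  if (!is.null(acc_df)) rownames(acc_df) <- NULL
  structure(
    list(accepted = acc_df, profiles = profiles,
         aggregate_on_t = agg_on, aggregate_off_t = agg_off,
         target = target, termination_reason = reason,
         log = do.call(rbind, log_rows)),
    class = "probe_set"
  )
}

#' @export
print.probe_set <- function(x, ...) {
  n <- if (is.null(x$accepted)) 0L else nrow(x$accepted)
  cat(sprintf(
    "probe_set: %d probe(s), aggregate on_t=%.2f off_t=%.2f (%s)\n",
    n, x$aggregate_on_t, x$aggregate_off_t, x$termination_reason))
  invisible(x)
}
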
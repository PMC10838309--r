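# Candidate scoring and rank-ordering by target-specific k-mer enrichment.
#
# Per candidate: r_m ("copy_num") sums the occurrence counts of the probe's
# k-mers inside the target interval, h_m ("total_genome_binding") sums them
# genome-wide, and k_b ("enrich_score") = r_m / h_m. Candidates are ordered
# by Normalized Rank
#     Nr = r_m / (max(r_m) * c1) + k_b / (max(k_b) * c2),
# maxima taken within the target's own candidate set, then thinned by the
# mer_cutoff redundancy filter: walking down the ranking, a candidate whose
# k-mer set overlaps the union of accepted candidates' k-mers by more than
# mer_cutoff is dropped. k-mer sets (not multisets) are used for the
# overlap proportion.

#' Score candidates by k-mer enrichment
#'
#' @param candidates Candidate data.frame from [mine_candidates()].
#' @param table A `kmer_count_table`.
#' @param target Single-row target interval.
#' @param assembly The [genome_assembly()].
#' @return The candidates with columns `r_m`, `h_m`, `k_b` appended;
#'   candidates with `h_m == 0` are dropped with a warning.
#' @export
score_candidates <- function(candidates, table, target, assembly) {
  if (nrow(candidates) == 0L) {
    candidates$r_m <- integer(0)
    candidates$h_m <- integer(0)
    candidates$k_b <- numeric(0)
    return(candidates)
  }
  rtab <- region_kmer_table(target, assembly, table$k)
  sc <- lapply(candidates$sequence, function(s)
    probe_kmer_counts(table, s, target, assembly, region_table = rtab))
  candidates$r_m <- vapply(sc, `[[`, integer(1), "r_m")
  candidates$h_m <- vapply(sc, `[[`, integer(1), "h_m")
  zero <- candidates$h_m == 0L
  if (any(zero)) {
    warning(sum(zero), " candidate(s) with zero genome-wide k-mer count dropped")
    candidates <- candidates[!zero, , drop = FALSE]
  }
  candidates$k_b <- candidates$r_m / candidates$h_m
  rownames(candidates) <- NULL
  candidates
}

#' Order candidates by Normalized Rank
#'
#' @param probes Scored candidate data.frame (from [score_candidates()]).
#' @param c1,c2 Positive weighting constants.
#' @return The data.frame with an `nr` column, sorted descending by `nr`;
#'   ties broken by lower genomic start, then lexicographic sequence.
#' @export
normalized_rank <- function(probes, c1 = 1, c2 = 1) {
  if (c1 <= 0 || c2 <= 0) stop("c1 and c2 must be positive")
  if (nrow(probes) == 0L) stop("cannot rank an empty candidate set")
  probes$nr <- probes$r_m / (max(probes$r_m) * c1) +
    probes$k_b / (max(probes$k_b) * c2)
  ord <- order(-probes$nr, probes$start, probes$sequence)
  out <- probes[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop rank-redundant candidates by shared k-mer composition
#'
#' @param ranked Data.frame sorted descending by `nr`.
#' @param mer_cutoff Maximum allowed proportion of a candidate's (distinct)
#'   k-mers already present in accepted higher-ranked candidates, in
#'   `[0, 1]`; overlap strictly above the cutoff rejects.
#' @param k k-mer length.
#' @return The surviving subsequence of `ranked` (order preserved).
#' @export
mer_cutoff_filter <- function(ranked, mer_cutoff, k) {
  stopifnot(mer_cutoff >= 0, mer_cutoff <= 1)
  if (nrow(ranked) == 0L) return(ranked)
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  keep <- logical(nrow(ranked))
  for (i in seq_len(nrow(ranked))) {
    kmers <- unique(seq_kmers(ranked$sequence[[i]], k))
    shared <- sum(vapply(kmers, function(km)
      !is.null(seen[[km]]), logical(1)))
    if (shared / length(kmers) > mer_cutoff) next
    keep[[i]] <- TRUE
    for (km in kmers) seen[[km]] <- TRUE
  }
  out <- ranked[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
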
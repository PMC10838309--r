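# Seed-and-extend enumeration of putative genomic binding sites.
#
# A precomputed exact-match index of all genome seed_length-mers anchors the
# search; every seed_length substring of the probe (and of its reverse
# complement, so both strands are always searched) is looked up, and each
# anchored locus is extended by local Smith-Waterman alignment (match +2,
# mismatch -6, gap open -5, gap extend -3, mirroring local-mode alignment
# scoring). Hits are kept iff score >= 1 + 4*ln(probe length), overlapping
# extensions collapse to the best-scoring site per locus and strand, and at
# most max_alignments hits are returned, best score first. Seed sensitivity
# to one mismatch is approximated by also probing all 1-mismatch variants of
# every seed while the genome index is small (< 1e7 positions); hit sets
# are not guaranteed identical to any external aligner's.

ALN_MATCH <- 2
ALN_MISMATCH <- -6
ALN_GAP_OPEN <- 5   # positive costs, Biostrings convention
ALN_GAP_EXT <- 3
SEED_MM_INDEX_LIMIT <- 1e7

.aligner_env <- new.env(parent = emptyenv())

substitution_matrix <- function() {
  if (is.null(.aligner_env$submat)) {
    letters <- c("A", "C", "G", "T", "N")
    m <- matrix(ALN_MISMATCH, 5L, 5L, dimnames = list(letters, letters))
    diag(m) <- ALN_MATCH
    m["N", "N"] <- ALN_MISMATCH  # N never rewards
    .aligner_env$submat <- m
  }
  .aligner_env$submat
}

#' Minimum qualifying local alignment score for a probe
#'
#' The `1 + 4*ln(L)` rule.
#'
#' @param probe_length Probe length in nt.
#' @return Minimum score.
#' @export
min_alignment_score <- function(probe_length) 1 + 4 * log(probe_length)

#' Build an exact-match seed index of an assembly
#'
#' @param assembly A [genome_assembly()].
#' @param seed_length Seed length (default 15).
#' @return An object of class `seed_index`; reusable across probes.
#' @export
seed_index <- function(assembly, seed_length = 15L) {
  stopifnot(inherits(assembly, "genome_assembly"), seed_length >= 1L)
  per_scaffold <- list()
  total <- 0L
  for (nm in names(assembly$scaffolds)) {
    kmers <- seq_kmers(assembly$scaffolds[[nm]], seed_length)
    if (length(kmers) == 0L) next
    ok <- !grepl("N", kmers, fixed = TRUE)
    pos0 <- which(ok) - 1L            # 0-based start positions
    e <- list2env(split(pos0, kmers[ok]), hash = TRUE,
                  parent = emptyenv())
    per_scaffold[[nm]] <- e
    total <- total + length(pos0)
  }
  structure(list(seed_length = as.integer(seed_length), index = per_scaffold,
                 n_positions = total),
            class = "seed_index")
}

# All 1-substitution variants of a seed string.
seed_variants <- function(seed) {
  chars <- strsplit(seed, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (i in seq_along(chars)) {
    for (b in setdiff(bases, chars[[i]])) {
      v <- chars
      v[[i]] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}

# Anchors (0-based probe-start positions) for one oriented query sequence on
# one scaffold environment.
collect_anchors <- function(env, qseq, seed_length, with_mismatch) {
  L <- nchar(qseq)
  offs <- 0:(L - seed_length)
  seeds <- substring(qseq, offs + 1L, offs + seed_length)
  anchors <- integer(0)
  for (j in seq_along(offs)) {
    keys <- seeds[[j]]
    if (with_mismatch) keys <- c(keys, seed_variants(keys))
    for (key in keys) {
      hits <- env[[key]]
      if (!is.null(hits)) anchors <- c(anchors, hits - offs[[j]])
    }
  }
  sort(unique(anchors))
}

empty_hits <- function() {
  data.frame(scaffold = character(0), start = integer(0), end = integer(0),
             strand = character(0), score = numeric(0),
             probe_row = character(0), target_row = character(0),
             stringsAsFactors = FALSE)
}

#' Enumerate genomic binding sites for a probe
#'
#' @param probe Probe sequence (`{A,C,G,T}`, length >= `seed_length`).
#' @param assembly A [genome_assembly()].
#' @param seed_length Seed length (default 15).
#' @param max_alignments Cap on returned hits (default 500000).
#' @param index Optional precomputed [seed_index()] (must match
#'   `seed_length`); built on the fly when `NULL`.
#' @return Data.frame of hits, best score first (ties by scaffold order,
#'   then start): `scaffold`, `start`, `end` (0-based half-open,
#'   forward-strand frame), `strand` (`+`/`-`), `score`, and the aligned
#'   `probe_row` / `target_row` strings (`-` for gaps; for `-` strand hits
#'   the target row is the reverse complement of the genomic slice, so rows
#'   are directly hybridization-comparable).
#' @export
align_probe <- function(probe, assembly, seed_length = 15L,
                        max_alignments = 500000L, index = NULL) {
  Lp <- nchar(probe)
  if (Lp < seed_length) {
    stop("probe (", Lp, " nt) shorter than seed_length (", seed_length, ")")
  }
  check_acgt(probe, "probe")
  if (is.null(index)) index <- seed_index(assembly, seed_length)
  stopifnot(inherits(index, "seed_index"),
            index$seed_length == seed_length)
  with_mm <- index$n_positions < SEED_MM_INDEX_LIMIT
  pad <- 12L
  min_score <- min_alignment_score(Lp)
  submat <- substitution_matrix()
  probe_ds <- Biostrings::DNAString(probe)
  rc_probe <- revcomp(probe)

  rows <- list()
  for (nm in names(index$index)) {
    env <- index$index[[nm]]
    scaf_seq <- assembly$scaffolds[[nm]]
    scaf_len <- nchar(scaf_seq)
    for (strand in c("+", "-")) {
      qseq <- if (strand == "+") probe else rc_probe
      anchors <- collect_anchors(env, qseq, seed_length, with_mm)
      for (a in anchors) {
        ws <- max(0L, a - pad)
        we <- min(scaf_len, a + Lp + pad)
        if (we - ws < seed_length) next
        slice <- substr(scaf_seq, ws + 1L, we)
        oriented <- if (strand == "+") slice else revcomp(slice)
        pa <- Biostrings::pairwiseAlignment(
          probe_ds, Biostrings::DNAString(oriented), type = "local",
          substitutionMatrix = submat,
          gapOpening = ALN_GAP_OPEN, gapExtension = ALN_GAP_EXT)
        sc <- Biostrings::score(pa)
        if (sc < min_score) next
        sstart <- Biostrings::start(Biostrings::subject(pa))
        send <- Biostrings::end(Biostrings::subject(pa))
        slice_len <- we - ws
        if (strand == "+") {
          g_start <- ws + sstart - 1L
          g_end <- ws + send
        } else {
          g_start <- ws + slice_len - send
          g_end <- ws + slice_len - sstart + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold = nm, start = g_start, end = g_end, strand = strand,
          score = sc,
          probe_row = as.character(Biostrings::alignedPattern(pa)),
          target_row = as.character(Biostrings::alignedSubject(pa)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty_hits())
  hits <- do.call(rbind, rows)
  scaf_rank <- match(hits$scaffold, names(assembly$scaffolds))
  hits <- hits[order(-hits$score, scaf_rank, hits$start), , drop = FALSE]

  # collapse overlapping extensions: best score wins per locus/strand
  keep <- logical(nrow(hits))
  kept <- list()  # per scaffold/strand: matrix of kept [start, end)
  for (i in seq_len(nrow(hits))) {
    key <- paste0(hits$scaffold[[i]], hits$strand[[i]])
    iv <- kept[[key]]
    if (is.null(iv) ||
        !any(hits$start[[i]] < iv[, 2L] & hits$end[[i]] > iv[, 1L])) {
      keep[[i]] <- TRUE
      kept[[key]] <- rbind(iv, c(hits$start[[i]], hits$end[[i]]))
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- utils::head(hits, max_alignments)
  rownames(hits) <- NULL
  hits
}

#' Aligned probe/target rows of a hit
#'
#' @param hit A single-row hit data.frame from [align_probe()].
#' @return List with `probe_row` and `target_row`.
#' @export
pairwise <- function(hit) {
  stopifnot(nrow(hit) == 1L)
  list(probe_row = hit$probe_row, target_row = hit$target_row)
}

#' Recompute a local alignment score from its aligned rows
#'
#' Matches score `+2`, mismatches `-6`; each maximal gap run costs
#' `5 + 3 * length`. Used to check stored scores for consistency.
#'
#' @param probe_row,target_row Equal-length aligned strings.
#' @return Numeric score.
#' @export
alignment_score_from_rows <- function(probe_row, target_row) {
  p <- strsplit(probe_row, "", fixed = TRUE)[[1L]]
  t <- strsplit(target_row, "", fixed = TRUE)[[1L]]
  stopifnot(length(p) == length(t))
  gap <- p == "-" | t == "-"
  sc <- sum(ifelse(p[!gap] == t[!gap], ALN_MATCH, ALN_MISMATCH))
  if (any(gap)) {
    runs <- rle(gap)
    gap_lens <- runs$lengths[runs$values]
    sc <- sc - sum(ALN_GAP_OPEN + ALN_GAP_EXT * gap_lens)
  }
  sc
}

#' Export alignment hits as BED6
#'
#' @param hits Hit data.frame from [align_probe()].
#' @param probe_id Name column value.
#' @param path Output path.
#' @export
write_hits_bed <- function(hits, probe_id, path) {
  lines <- paste(hits$scaffold, hits$start, hits$end, probe_id,
                 formatC(hits$score, format = "f", digits = 1L),
                 hits$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
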
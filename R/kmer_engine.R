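# Whole-genome k-mer counting and per-position / per-probe count queries.
#
# Counting is strand-specific: k-mers are counted as written on the forward
# strand, with no canonicalization, so a probe's genome-wide count sum (H_m)
# and target count sum (R_m) reflect forward-strand occurrences only. This
# matters for interpreting the enrichment ratio K_b and is therefore stated
# here and in the vignette. Windows containing N contribute nothing. The
# table is an in-memory hash; the intended working scale is assemblies up to
# tens of megabases.

# All k-mer start windows of seq (1-based starts), NA-free; returns character
# vector possibly containing N.
seq_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  starts <- seq_len(L - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

#' Count all k-mers of an assembly
#'
#' @param assembly A [genome_assembly()].
#' @param k k-mer length (default 18).
#' @return An object of class `kmer_count_table`: list with `k` and `counts`
#'   (named integer vector, k-mer -> genome-wide occurrence count).
#' @export
count_kmers <- function(assembly, k = 18L) {
  stopifnot(inherits(assembly, "genome_assembly"), k >= 1L)
  if (all(assembly$lengths < k)) {
    stop("k = ", k, " exceeds the length of every scaffold; ",
         "the count table would be empty")
  }
  all_kmers <- unlist(lapply(assembly$scaffolds, seq_kmers, k = k),
                      use.names = FALSE)
  all_kmers <- all_kmers[!grepl("N", all_kmers, fixed = TRUE)]
  tab <- table(all_kmers)
  counts <- stats::setNames(as.integer(tab), names(tab))
  structure(list(k = as.integer(k), counts = counts),
            class = "kmer_count_table")
}

#' @export
print.kmer_count_table <- function(x, ...) {
  cat("kmer_count_table: k =", x$k, ",", length(x$counts),
      "distinct k-mers,", sum(x$counts), "total occurrences\n")
  invisible(x)
}

#' Dump a k-mer count table to a 2-column TSV
#'
#' @param table A `kmer_count_table`.
#' @param path Output path.
#' @export
write_kmer_table <- function(table, path) {
  writeLines(paste(names(table$counts), table$counts, sep = "\t"), path)
  invisible(path)
}

#' Load a k-mer count table from a 2-column TSV
#'
#' @param path Path written by [write_kmer_table()].
#' @return A `kmer_count_table`.
#' @export
read_kmer_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer"))
  k <- unique(nchar(df[[1L]]))
  if (length(k) != 1L) stop("mixed k-mer lengths in table file")
  structure(list(k = as.integer(k),
                 counts = stats::setNames(df[[2L]], df[[1L]])),
            class = "kmer_count_table")
}

#' Per-position genome-wide k-mer counts along a sequence
#'
#' Position `i` (1-based in the returned vector; 0-based along the sequence)
#' holds the table count of the k-mer starting there; positions whose k-mer
#' contains N hold 0.
#'
#' @param table A `kmer_count_table`.
#' @param seq A scaffold sequence.
#' @return Integer vector of length `max(0, nchar(seq) - k + 1)`.
#' @export
position_counts <- function(table, seq) {
  stopifnot(inherits(table, "kmer_count_table"))
  kmers <- seq_kmers(seq, table$k)
  if (length(kmers) == 0L) return(integer(0))
  counts <- unname(table$counts[kmers])
  counts[is.na(counts)] <- 0L
  counts[grepl("N", kmers, fixed = TRUE)] <- 0L
  counts
}

#' Aggregate k-mer counts of a probe within a target region and genome-wide
#'
#' `h_m` sums the genome-wide table counts of the probe's constituent
#' k-mers; `r_m` sums, over the same k-mers, their occurrence counts inside
#' the region only (computed by a direct scan of the region sequence, so
#' occurrences straddling the region boundary are not counted).
#'
#' @param table A `kmer_count_table` built from `assembly`.
#' @param probe Probe sequence (length >= k, no N).
#' @param region A single-row interval data.frame (the target).
#' @param assembly The [genome_assembly()].
#' @param region_table Optional precomputed [region_kmer_table()] for
#'   `region` (avoids rescanning the region per probe).
#' @return List with integer elements `r_m` and `h_m` (`0 <= r_m <= h_m`).
#' @export
probe_kmer_counts <- function(table, probe, region, assembly,
                              region_table = NULL) {
  stopifnot(inherits(table, "kmer_count_table"), nrow(region) == 1L)
  k <- table$k
  if (nchar(probe) < k) {
    stop("probe (", nchar(probe), " nt) is shorter than k = ", k)
  }
  pk <- seq_kmers(probe, k)
  if (any(grepl("N", pk, fixed = TRUE))) stop("probe contains N")
  h <- table$counts[pk]
  h[is.na(h)] <- 0L
  if (is.null(region_table)) {
    region_table <- region_kmer_table(region, assembly, k)
  }
  r <- region_table[pk]
  r[is.na(r)] <- 0L
  list(r_m = as.integer(sum(r)), h_m = as.integer(sum(h)))
}

#' Occurrence counts of all k-mers within a region
#'
#' Direct scan of the region sequence; k-mers straddling the region
#' boundary are not counted. N-containing windows are dropped.
#'
#' @param region Single-row interval data.frame.
#' @param assembly A [genome_assembly()].
#' @param k k-mer length.
#' @return Named integer vector, k-mer -> count within the region.
#' @export
region_kmer_table <- function(region, assembly, k) {
  region_seq <- assembly_slice(assembly, region$scaffold, region$start,
                               region$end)
  rk <- seq_kmers(region_seq, k)
  rk <- rk[!grepl("N", rk, fixed = TRUE)]
  tab <- table(rk)
  stats::setNames(as.integer(tab), names(tab))
}
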
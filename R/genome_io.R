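# Genome and interval I/O.
#
# All coordinates in this package are 0-based, half-open (BED convention).
# Sequences are uppercase strings over {A,C,G,T,N}: lowercase (soft-masked)
# bases are uppercased and treated as ordinary sequence, U is mapped to T,
# and any other character (IUPAC ambiguity codes included) collapses to N so
# that unpolished assemblies load; N-containing windows are excluded
# downstream rather than erroring here.

#' Construct a genome assembly
#'
#' @param seqs Named character vector: scaffold name -> sequence. Sequences
#'   are normalized to uppercase `{A,C,G,T,N}` (`U` becomes `T`, anything
#'   else becomes `N`).
#' @return An object of class `genome_assembly`: a list with elements
#'   `scaffolds` (named character vector of sequences) and `lengths`
#'   (named integer vector of sequence lengths, same order).
#' @export
genome_assembly <- function(seqs) {
  if (length(seqs) == 0L) stop("assembly must contain at least one scaffold")
  nm <- names(seqs)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("every scaffold must have a non-empty name")
  }
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0L) {
    stop("duplicate scaffold name: ", dup[[1L]])
  }
  seqs <- normalize_dna(seqs)
  structure(
    list(
      scaffolds = seqs,
      lengths = stats::setNames(nchar(seqs), nm)
    ),
    class = "genome_assembly"
  )
}

# Uppercase, U->T, everything outside ACGT -> N.
normalize_dna <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  gsub("[^ACGT]", "N", x, perl = TRUE)
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("genome_assembly with", length(x$scaffolds), "scaffold(s),",
      sum(x$lengths), "bp total\n")
  for (nm in utils::head(names(x$scaffolds), 10L)) {
    cat(sprintf("  %s  %d bp\n", nm, x$lengths[[nm]]))
  }
  invisible(x)
}

#' Read a genome assembly from FASTA
#'
#' Scaffold names are taken as the first whitespace-delimited token of each
#' header line. Duplicate names are a hard error.
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return A [genome_assembly()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("FASTA file is empty: ", path)
  nms <- sub("\\s.*$", "", names(recs))
  seqs <- stats::setNames(as.character(recs), nms)
  genome_assembly(seqs)
}

#' Write a genome assembly to FASTA
#'
#' @param assembly A [genome_assembly()].
#' @param path Output path.
#' @export
write_fasta <- function(assembly, path) {
  stopifnot(inherits(assembly, "genome_assembly"))
  x <- Biostrings::DNAStringSet(assembly$scaffolds)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a chrom.sizes table
#'
#' Two-column tab-separated text: scaffold name, length in bp.
#'
#' @param path Path to the file.
#' @return Named integer vector of scaffold lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("chrom.sizes file is empty: ", path)
  out <- integer(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 2L) {
      stop("malformed chrom.sizes line ", i, ": expected 2 tab-separated fields")
    }
    len <- suppressWarnings(as.integer(f[[2L]]))
    if (is.na(len) || len <= 0L) {
      stop("non-positive or non-integer length on chrom.sizes line ", i,
           ": '", f[[2L]], "'")
    }
    out[[f[[1L]]]] <- len
  }
  out
}

#' Write a chrom.sizes table for an assembly
#'
#' @param assembly A [genome_assembly()].
#' @param path Output path.
#' @export
write_chrom_sizes <- function(assembly, path) {
  stopifnot(inherits(assembly, "genome_assembly"))
  writeLines(paste(names(assembly$lengths), assembly$lengths, sep = "\t"), path)
  invisible(path)
}

#' Construct a table of BED intervals
#'
#' @param scaffold Character vector of scaffold names.
#' @param start,end Integer vectors, 0-based half-open.
#' @param name Optional character vector of labels (NA allowed).
#' @param assembly Optional [genome_assembly()] to validate bounds against.
#' @return A data.frame with columns `scaffold`, `start`, `end`, `name`.
#' @export
bed_intervals <- function(scaffold, start, end, name = NA_character_,
                          assembly = NULL) {
  df <- data.frame(
    scaffold = as.character(scaffold),
    start = as.integer(start),
    end = as.integer(end),
    name = as.character(name),
    stringsAsFactors = FALSE
  )
  validate_intervals(df, assembly)
  df
}

validate_intervals <- function(df, assembly = NULL) {
  bad <- which(df$start < 0L | df$start >= df$end)
  if (length(bad) > 0L) {
    stop("invalid interval at row ", bad[[1L]],
         ": require 0 <= start < end (got ", df$start[bad[[1L]]], ", ",
         df$end[bad[[1L]]], ")")
  }
  if (!is.null(assembly)) {
    unknown <- setdiff(unique(df$scaffold), names(assembly$lengths))
    if (length(unknown) > 0L) {
      stop("unknown scaffold in intervals: ", unknown[[1L]])
    }
    lens <- assembly$lengths[df$scaffold]
    oob <- which(df$end > lens)
    if (length(oob) > 0L) {
      stop("interval out of scaffold bounds at row ", oob[[1L]], ": end ",
           df$end[oob[[1L]]], " > ", lens[oob[[1L]]], " (", df$scaffold[oob[[1L]]], ")")
    }
  }
  invisible(df)
}

#' Read a BED3+ file
#'
#' @param path Path to a tab-separated BED file with at least 3 columns.
#' @param assembly Optional [genome_assembly()]; when given, every interval
#'   is validated against scaffold bounds.
#' @return A data.frame of intervals as from [bed_intervals()].
#' @export
read_bed <- function(path, assembly = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(bed_intervals(character(0), integer(0), integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(fields, length, integer(1))
  if (any(ncol < 3L)) {
    stop("BED line ", which(ncol < 3L)[[1L]], " has fewer than 3 columns")
  }
  scaffold <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("non-integer coordinate in BED file at line ",
         which(is.na(start) | is.na(end))[[1L]])
  }
  name <- ifelse(ncol >= 4L,
                 vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_,
                        character(1)),
                 NA_character_)
  bed_intervals(scaffold, start, end, name, assembly = assembly)
}

#' Write intervals as BED
#'
#' Writes BED3 when no interval has a name, BED4 (or more, if extra numeric
#' score columns are supplied) otherwise.
#'
#' @param df Interval data.frame (columns `scaffold`, `start`, `end`,
#'   optionally `name` and `score`).
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  cols <- list(df$scaffold, df$start, df$end)
  if (!is.null(df$name) && any(!is.na(df$name))) {
    cols <- c(cols, list(ifelse(is.na(df$name), ".", df$name)))
    if (!is.null(df$score)) cols <- c(cols, list(df$score))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a 4-column bedGraph track
#'
#' @param df Data.frame with columns `scaffold`, `start`, `end`, `value`.
#' @param path Output path.
#' @param digits Decimal places for the value column (ignored for integers).
#' @export
write_bedgraph <- function(df, path, digits = 4L) {
  val <- if (is.integer(df$value)) as.character(df$value) else
    formatC(df$value, format = "f", digits = digits)
  writeLines(paste(df$scaffold, df$start, df$end, val, sep = "\t"), path)
  invisible(path)
}

#' Write a tab-separated table
#'
#' Floating-point columns are written at 4 decimal places.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(out[[j]], format = "f", digits = 4L)
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path Path to a TSV with a header row.
#' @return A data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# Slice assembly sequence on [start, end) 0-based half-open coordinates.
assembly_slice <- function(assembly, scaffold, start, end) {
  seq <- assembly$scaffolds[[scaffold]]
  if (is.null(seq)) stop("unknown scaffold: ", scaffold)
  substr(seq, start + 1L, end)
}

# Reverse complement for plain character sequences (N maps to N).
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                                     collapse = ""), character(1), USE.NAMES = FALSE))
}
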
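# Deterministic synthetic genomes with planted tandem-repeat arrays.
#
# The generator emulates a satellite-like target: a tandem array of a single
# monomer (default 171 bp, the alpha-satellite monomer length) with 30
# copies carrying independent per-copy substitution divergence, embedded in
# i.i.d. random background so that the default single-scaffold genome is
# exactly 50 kb. Optionally a decoy array with stated identity to the target
# monomer is planted downstream, to exercise off-target screening.

#' Specify a synthetic tandem-repeat fixture
#'
#' @param monomer_length Monomer length in bp.
#' @param copies Number of tandem copies of the monomer.
#' @param divergence Per-base substitution probability applied independently
#'   to each copy (in `[0, 1)`); 0 plants exact copies.
#' @param flank_length Random background length on each side of the array, bp.
#' @param gc_percent Background (and monomer) GC content, percent.
#' @param decoy_identity Optional: if non-`NULL`, a second array is planted
#'   whose monomer shares this fraction of identical positions with the
#'   target monomer.
#' @param decoy_copies Copies in the decoy array.
#' @param seed Integer RNG seed; fixes all randomness.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(monomer_length = 171L, copies = 30L,
                         divergence = 0.02, flank_length = 22435L,
                         gc_percent = 50, decoy_identity = NULL,
                         decoy_copies = copies, seed = 1L) {
  stopifnot(monomer_length >= 1L, copies >= 1L,
            divergence >= 0, divergence < 1,
            flank_length >= 0L, gc_percent >= 0, gc_percent <= 100)
  if (!is.null(decoy_identity)) {
    stopifnot(decoy_identity >= 0, decoy_identity <= 1)
  }
  structure(
    list(monomer_length = as.integer(monomer_length),
         copies = as.integer(copies), divergence = divergence,
         flank_length = as.integer(flank_length), gc_percent = gc_percent,
         decoy_identity = decoy_identity,
         decoy_copies = as.integer(decoy_copies), seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

random_dna <- function(n, gc_percent = 50) {
  if (n == 0L) return("")
  p_gc <- gc_percent / 100
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - p_gc) / 2, p_gc / 2, p_gc / 2, (1 - p_gc) / 2)),
        collapse = "")
}

# Substitute each position independently with probability p; substitutions
# always change the base.
mutate_seq <- function(seq, p) {
  if (p <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < p)
  for (i in hit) {
    chars[[i]] <- sample(setdiff(c("A", "C", "G", "T"), chars[[i]]), 1L)
  }
  paste(chars, collapse = "")
}

# Force a monomer to an exact identity fraction with the original by
# substituting a fixed set of positions.
diverge_to_identity <- function(seq, identity) {
  n <- nchar(seq)
  n_mut <- round((1 - identity) * n)
  if (n_mut == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (i in sample.int(n, n_mut)) {
    chars[[i]] <- sample(setdiff(c("A", "C", "G", "T"), chars[[i]]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic genome with planted tandem arrays
#'
#' Layout on a single scaffold `chrSim`: flank, target array, flank, and
#' (when a decoy is requested) decoy array plus one more flank. Ground-truth
#' intervals exactly delimit the planted arrays. Identical seeds produce
#' byte-identical output.
#'
#' @param spec A [fixture_spec()].
#' @return A list with elements `assembly` ([genome_assembly()]), `truth`
#'   (interval data.frame; names `target`, optionally `decoy`), and
#'   `monomers` (named character vector of monomer sequences).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  monomer <- random_dna(spec$monomer_length, spec$gc_percent)
  array1 <- paste(vapply(seq_len(spec$copies),
                         function(i) mutate_seq(monomer, spec$divergence),
                         character(1)), collapse = "")
  left <- random_dna(spec$flank_length, spec$gc_percent)
  right <- random_dna(spec$flank_length, spec$gc_percent)

  parts <- c(left, array1, right)
  t_start <- nchar(left)
  t_end <- t_start + nchar(array1)
  truth <- bed_intervals("chrSim", t_start, t_end, "target")
  monomers <- c(target = monomer)

  if (!is.null(spec$decoy_identity)) {
    decoy_monomer <- diverge_to_identity(monomer, spec$decoy_identity)
    decoy <- paste(vapply(seq_len(spec$decoy_copies),
                          function(i) mutate_seq(decoy_monomer, spec$divergence),
                          character(1)), collapse = "")
    d_start <- t_end + nchar(right)
    d_end <- d_start + nchar(decoy)
    parts <- c(parts, decoy, random_dna(spec$flank_length, spec$gc_percent))
    truth <- rbind(truth,
                   bed_intervals("chrSim", d_start, d_end, "decoy"))
    monomers <- c(monomers, decoy = decoy_monomer)
  }

  assembly <- genome_assembly(c(chrSim = paste(parts, collapse = "")))
  list(assembly = assembly, truth = truth, monomers = monomers)
}

#' Write a fixture to disk
#'
#' Emits FASTA, chrom.sizes and ground-truth BED, plus the spec itself as a
#' YAML reproducibility record.
#'
#' @param fixture Output of [generate_fixture()].
#' @param dir Output directory (created if needed).
#' @param spec The [fixture_spec()] used (recorded alongside).
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(fixture, dir, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fixture$assembly, file.path(dir, "genome.fa"))
  write_chrom_sizes(fixture$assembly, file.path(dir, "genome.chrom.sizes"))
  write_bed(fixture$truth, file.path(dir, "truth.bed"))
  if (!is.null(spec)) {
    yaml::write_yaml(unclass(spec), file.path(dir, "fixture_spec.yml"))
  }
  invisible(dir)
}
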
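# Nearest-neighbor DNA hybridization thermodynamics.
#
# Unified dinucleotide dH/dS parameters (Watson-Crick stacks, with
# initiation terms for terminal A.T and G.C pairs) are shipped as a
# versioned TSV in extdata. Two quantities are derived from them:
#
#  * melting_temperature(): probe Tm with monovalent-salt entropy correction
#    (0.368 * n_stacks * ln[Na+]) and a linear formamide correction of
#    -0.65 degC per percent formamide.
#
#  * duplex_probability(): a two-state (bound/unbound) equilibrium fraction
#    for a probe paired with a derived alignment site under hybridization
#    conditions (default 69.5 degC, 0.39 M Na+, equal strand concentrations
#    of 1e-6 M). dG accumulates over matched nearest-neighbor stacks;
#    every mismatched or gapped column contributes a destabilizing penalty
#    equivalent to +1.0 kcal/mol at the reference temperature, implemented
#    as an entropic term so the duplex fraction is non-increasing in
#    temperature for every alignment pair. The fraction duplexed solves the
#    bimolecular mass-action quadratic and is clamped to [0, 1].

.thermo_env <- new.env(parent = emptyenv())

R_GAS <- 1.987204  # cal / (mol K)
PENALTY_REF_T <- 69.5 + 273.15  # K; the +1.0 kcal/mol penalty is set here

nn_params <- function() {
  if (is.null(.thermo_env$nn)) {
    path <- system.file("extdata", "nn_dna_unified_v1.tsv", package = "repfish")
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    .thermo_env$nn <- list(
      dH = stats::setNames(df$dH_kcal_mol, df$dinucleotide),
      dS = stats::setNames(df$dS_cal_mol_K, df$dinucleotide)
    )
  }
  .thermo_env$nn
}

#' Hybridization condition model
#'
#' @param temperature_celsius Hybridization temperature, degC.
#' @param sodium_molar Monovalent cation concentration, mol/L.
#' @param magnesium_molar Divalent cation concentration, mol/L (recorded but
#'   no divalent correction is applied; keep at 0).
#' @param formamide_percent Formamide, % v/v, used only where a Tm is taken
#'   (the duplex model's temperature already encodes stringency).
#' @param strand_concentration Per-strand concentration, mol/L (equal
#'   strands).
#' @return A list of class `thermo_model`.
#' @export
thermo_model <- function(temperature_celsius = 69.5, sodium_molar = 0.39,
                         magnesium_molar = 0, formamide_percent = 0,
                         strand_concentration = 1e-6) {
  stopifnot(is.finite(temperature_celsius), sodium_molar > 0,
            magnesium_molar >= 0, strand_concentration >= 0)
  structure(list(temperature_celsius = temperature_celsius,
                 sodium_molar = sodium_molar,
                 magnesium_molar = magnesium_molar,
                 formamide_percent = formamide_percent,
                 strand_concentration = strand_concentration),
            class = "thermo_model")
}

check_acgt <- function(seq, what = "sequence") {
  if (grepl("[^ACGT]", seq)) {
    stop(what, " contains characters outside {A,C,G,T}: ", seq)
  }
}

# Sum of NN dH (kcal/mol) and dS (cal/mol K) over all stacks of a duplex
# given one strand, plus initiation terms for both ends.
nn_sums <- function(seq) {
  nn <- nn_params()
  L <- nchar(seq)
  stacks <- substring(seq, 1:(L - 1L), 2:L)
  ends <- c(substr(seq, 1L, 1L), substr(seq, L, L))
  init_keys <- ifelse(ends %in% c("G", "C"), "init_GC", "init_AT")
  list(dH = sum(nn$dH[stacks]) + sum(nn$dH[init_keys]),
       dS = sum(nn$dS[stacks]) + sum(nn$dS[init_keys]),
       n_stacks = L - 1L)
}

#' Nearest-neighbor melting temperature
#'
#' Tm of the probe against its perfect complement under the two-state model:
#' `Tm = 1000*dH / (dS_salt + R*ln(Ct/4)) - 273.15 - 0.65*formamide`,
#' where `dS_salt = dS + 0.368*n_stacks*ln([Na+])` and `Ct` is the total
#' strand concentration (twice the per-strand value, strands equal).
#'
#' @param seq Probe sequence (length >= 2, `{A,C,G,T}` only).
#' @param sodium_molar Monovalent salt, mol/L.
#' @param formamide_percent Formamide, % v/v.
#' @param strand_concentration Per-strand concentration, mol/L.
#' @return Tm in degC.
#' @export
melting_temperature <- function(seq, sodium_molar = 0.39,
                                formamide_percent = 50,
                                strand_concentration = 1e-6) {
  if (nchar(seq) < 2L) stop("sequence must be at least 2 nt")
  check_acgt(seq, "probe")
  s <- nn_sums(seq)
  dS_salt <- s$dS + 0.368 * s$n_stacks * log(sodium_molar)
  ct <- 2 * strand_concentration
  tm_k <- 1000 * s$dH / (dS_salt + R_GAS * log(ct / 4))
  tm_k - 273.15 - 0.65 * formamide_percent
}

#' GC content of a sequence, percent
#'
#' @param seq Sequence string.
#' @return Percent of positions that are G or C.
#' @export
gc_percent <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  100 * mean(chars %in% c("G", "C"))
}

#' Two-state duplex-formation probability for an alignment pair
#'
#' The two rows are the probe and the (hybridization-oriented) target site
#' from a local alignment, equal length, `-` for gaps. A column is a match
#' iff both characters are equal and in `{A,C,G,T}`; consecutive matched
#' columns contribute the nearest-neighbor stack of the probe row, every
#' other column contributes the destabilizing penalty. `p_dups` is the
#' equilibrium fraction of probe molecules in duplex at the model's
#' temperature, salt and strand concentration.
#'
#' @param probe_row Aligned probe string.
#' @param target_row Aligned target string (same length).
#' @param model A [thermo_model()].
#' @return `p_dups` in `[0, 1]`.
#' @export
duplex_probability <- function(probe_row, target_row, model = thermo_model()) {
  if (nchar(probe_row) != nchar(target_row)) {
    stop("aligned rows differ in length (", nchar(probe_row), " vs ",
         nchar(target_row), ")")
  }
  L <- nchar(probe_row)
  if (L == 0L) return(0)
  p <- strsplit(probe_row, "", fixed = TRUE)[[1L]]
  t <- strsplit(target_row, "", fixed = TRUE)[[1L]]
  acgt <- c("A", "C", "G", "T")
  match_col <- p == t & p %in% acgt
  n_bad <- sum(!match_col)

  nn <- nn_params()
  dH <- 0
  dS <- 0
  n_stacks <- 0L
  if (L >= 2L) {
    stack_ok <- match_col[-L] & match_col[-1L]
    if (any(stack_ok)) {
      keys <- paste0(p[-L], p[-1L])[stack_ok]
      dH <- sum(nn$dH[keys])
      dS <- sum(nn$dS[keys])
      n_stacks <- sum(stack_ok)
    }
  }
  # initiation terms for matched terminal columns of the duplexed region
  matched_idx <- which(match_col)
  if (length(matched_idx) > 0L) {
    ends <- p[c(matched_idx[[1L]], matched_idx[[length(matched_idx)]])]
    init_keys <- ifelse(ends %in% c("G", "C"), "init_GC", "init_AT")
    dH <- dH + sum(nn$dH[init_keys])
    dS <- dS + sum(nn$dS[init_keys])
  }
  dS <- dS + 0.368 * n_stacks * log(model$sodium_molar)
  # mismatch/gap penalty: +1.0 kcal/mol at the reference temperature,
  # carried as entropy so dG_pen scales with T and dK/dT stays <= 0
  dS <- dS - n_bad * 1000 / PENALTY_REF_T

  temp_k <- model$temperature_celsius + 273.15
  dG <- dH - temp_k * dS / 1000  # kcal/mol
  K <- exp(-dG * 1000 / (R_GAS * temp_k))
  a <- K * model$strand_concentration
  if (!is.finite(a)) return(1)
  if (a <= 0) return(0)
  x <- (2 * a + 1 - sqrt(4 * a + 1)) / (2 * a)
  min(max(x, 0), 1)
}
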
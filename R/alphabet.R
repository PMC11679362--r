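#' @title Residue alphabet and mass tables
#' @name alphabet
#' @description Canonical amino-acid alphabet, Schechter-Berger subsite
#' labels and monoisotopic residue masses used throughout the package.
NULL

#' The 20 canonical amino acids, one-letter codes, alphabetical order.
#'
#' This fixed ordering is used for every specificity-matrix row so that
#' serialized matrices diff cleanly between runs.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Schechter-Berger subsite labels flanking the scissile bond,
#' substrate side, N- to C-terminal order: P2-P1 | P1'-P2'.
#' @export
SUBSITES <- c("P2", "P1", "P1'", "P2'")

# Internal, syntactically valid column names for the four subsites.
SUBSITE_COLS <- c("P2", "P1", "P1p", "P2p")

# Monoisotopic residue (not free amino acid) masses in Da.
MONOISOTOPIC_MASS <- c(
  A =  71.03711, C = 103.00919, D = 115.02694, E = 129.04259,
  F = 147.06841, G =  57.02146, H = 137.05891, I = 113.08406,
  K = 128.09496, L = 113.08406, M = 131.04049, N = 114.04293,
  P =  97.05276, Q = 128.05858, R = 156.10111, S =  87.03203,
  T = 101.04768, V =  99.06841, W = 186.07931, Y = 163.06333
)

WATER_MONOISOTOPIC <- 18.0105646863

#' Monoisotopic peptide mass
#'
#' Sum of monoisotopic residue masses plus one water, in Da. Used by the
#' digestion simulator to emulate a 10 kDa ultrafiltration cutoff.
#'
#' @param sequence Character vector of peptide sequences (canonical
#'   residues only).
#' @return Numeric vector of masses in Da.
#' @examples
#' peptide_mass("PEPTIDE")
#' @export
peptide_mass <- function(sequence) {
  vapply(strsplit(toupper(sequence), ""), function(aa) {
    bad <- setdiff(aa, names(MONOISOTOPIC_MASS))
    if (length(bad) > 0)
      stop("non-canonical residue(s) in peptide: ",
           paste(unique(bad), collapse = ", "))
    sum(MONOISOTOPIC_MASS[aa]) + WATER_MONOISOTOPIC
  }, numeric(1))
}

# Split sequences into single-residue character vectors (internal).
seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)
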
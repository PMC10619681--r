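# Monoisotopic mass constants. Residue masses are the dehydrated (in-chain)
# forms, so a glycan or peptide neutral mass is sum(residues) + water.

#' Monosaccharide residue masses and mass-spectrometry constants
#'
#' Monoisotopic residue masses (Da) of the four-monomer glycan alphabet used
#' throughout the package (HexNAc, Hex, Fuc, NeuAc), together with the proton
#' mass, the mass of water and the C12/C13 isotope spacing.
#'
#' @format A named numeric vector of residue masses in Da.
#' @examples
#' monosaccharide_masses()
#' @export
monosaccharide_masses <- function() {
  c(hexnac = 203.07937, hex = 162.05282, fuc = 146.05791, neuac = 291.09542)
}

#' @rdname monosaccharide_masses
#' @export
mass_proton <- function() 1.007276

#' @rdname monosaccharide_masses
#' @export
mass_water <- function() 18.010565

#' @rdname monosaccharide_masses
#' @export
mass_isotope_spacing <- function() 1.003355

# Amino-acid monoisotopic residue masses (Da), standard 20-letter alphabet.
aa_residue_masses <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# Carbamidomethylation of cysteine (fixed modification in the search setup).
CYS_CARBAMIDOMETHYL <- 57.02146
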
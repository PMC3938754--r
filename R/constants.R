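#' Physical constants used in energy bookkeeping
#'
#' All molar energies inside the package are carried in kJ/mol; per-molecule
#' energies (J) are obtained by multiplying by 1000 and dividing by Avogadro's
#' number. Free-energy grids for stability evolution are quoted in kcal/mol
#' (the unit the protein-engineering literature uses) and converted with the
#' factor 4.184 kJ/kcal at the point of use.
#'
#' @return A named list with `gas_constant` (kJ mol^-1 K^-1), `avogadro`
#'   (mol^-1) and `kcal_per_kj` (kcal per kJ, i.e. 1/4.184).
#' @examples
#' energy_constants()$gas_constant * 310.15 # RT at 37 C, kJ/mol
#' @export
energy_constants <- function() {
  list(
    gas_constant = 0.008314,
    avogadro     = 6.022e23,
    kcal_per_kj  = 1 / 4.184
  )
}

# internal shortcuts
.R_GAS  <- 0.008314
.AVOG   <- 6.022e23
.KJ_PER_KCAL <- 4.184

#' Molar mass of a protein from its chain length
#'
#' @param n_aa Number of amino-acid residues.
#' @param aa_mass Average residue mass, g/mol (default 130).
#' @return Molar mass in g/mol.
#' @examples
#' protein_mass(467) # average yeast protein, 60710 g/mol
#' @export
protein_mass <- function(n_aa, aa_mass = 130) {
  stopifnot(all(n_aa >= 1), aa_mass > 0)
  n_aa * aa_mass
}

#' Ribosomal rate constant for chain synthesis
#'
#' Chain elongation proceeds at roughly `aa_per_second` residues per second,
#' so the per-protein rate constant of ribosomal synthesis is
#' `aa_per_second / n_aa`.
#'
#' @param n_aa Number of residues.
#' @param aa_per_second Elongation rate, residues/s (default 15).
#' @return Rate constant in s^-1.
#' @examples
#' ribosome_rate_constant(467) # 3.21e-2 s^-1
#' @export
ribosome_rate_constant <- function(n_aa, aa_per_second = 15) {
  stopifnot(all(n_aa >= 1), aa_per_second > 0)
  aa_per_second / n_aa
}
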
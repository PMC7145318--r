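#' Physical constants and fixed molar masses
#'
#' Internal constants used throughout the package. Units: Angstrom, ps,
#' kJ/mol, K, elementary charges, g/mol. Conversions happen only at I/O
#' boundaries.
#'
#' @name sugartraj-constants
#' @keywords internal
NULL

# molar masses (g/mol); fixed standard values used for composition arithmetic
M_THAL <- 342.296
M_WATER <- 18.0153

# per-element atomic masses used by the generators (g/mol)
ELEMENT_MASSES <- c(H = 1.008, C = 12.011, O = 15.999, X = 1.0)

# Coulomb conversion constant f in kJ*Angstrom/(mol*e^2):
# f = e^2 * N_A / (4*pi*eps0 * 1e-10 m) / 1000
COULOMB_KJ_A <- {
  e <- 1.602176634e-19   # C
  na <- 6.02214076e23    # 1/mol
  eps0 <- 8.8541878128e-12 # F/m
  e^2 * na / (4 * pi * eps0 * 1e-10) / 1000
}

# gas constant, kJ/(mol K)
GAS_R <- 8.31446261815324e-3

# valid site-label tokens
SITE_LABELS <- c("O1", "O2", "O3", "O4", "Oe", "Ob",
                 paste0("C", 1:6), "Ho", "Ow", "Hw", "X")
MOLECULE_TYPES <- c("THAL", "WATER", "OTHER")

# hydroxyl (donor-capable / acceptor) oxygen labels on the disaccharide
HYDROXYL_LABELS <- c("O1", "O2", "O3", "O4")
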
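# Physical constants (CODATA-2018 exact values where defined) and element
# data. All package energetics are kcal/mol, lengths Angstrom, charges e.

.consts <- list(
  coulomb  = 332.0637,            # kcal A / (mol e^2), fixed for reproducibility
  kB       = 1.380649e-23,        # J / K
  h        = 6.62607015e-34,      # J s
  N_A      = 6.02214076e23,       # 1 / mol
  cal      = 4.184,               # J per thermochemical calorie
  c_cm     = 2.99792458e10,       # speed of light, cm / s
  amu      = 1.66053906660e-27,   # kg
  atm      = 101325               # Pa
)
.consts$R_kcal <- .consts$kB * .consts$N_A / (.consts$cal * 1000)  # kcal/(mol K)

# conversion: Hessian eigenvalue in kcal/mol/(amu A^2) -> angular freq^2 in s^-2
.consts$freq_conv <- (.consts$cal * 1000 / .consts$N_A) /
  (.consts$amu * 1e-20)

#' Physical constants used by the package
#'
#' Returns the pinned constants table (CODATA-2018 where exact) behind every
#' thermodynamic and spectroscopic conversion in the package: the Coulomb
#' constant used by all electrostatics, Boltzmann and Planck constants, the
#' molar gas constant in kcal/(mol K), and unit conversion factors.
#'
#' @return A tibble with columns `constant`, `value`, `unit`.
#' @export
#' @examples
#' physical_constants()
physical_constants <- function() {
  tibble::tibble(
    constant = c("coulomb", "k_B", "h", "N_A", "R", "cal", "c", "amu", "atm"),
    value = c(.consts$coulomb, .consts$kB, .consts$h, .consts$N_A,
              .consts$R_kcal, .consts$cal, .consts$c_cm, .consts$amu,
              .consts$atm),
    unit = c("kcal A mol-1 e-2", "J K-1", "J s", "mol-1", "kcal mol-1 K-1",
             "J cal-1", "cm s-1", "kg", "Pa")
  )
}

# element -> (mass amu, covalent radius A); enough for organic solutes + water
.elements <- data.frame(
  element = c("H", "C", "N", "O", "F", "P", "S", "Cl"),
  mass    = c(1.008, 12.011, 14.007, 15.999, 18.998, 30.974, 32.06, 35.45),
  r_cov   = c(0.31, 0.76, 0.71, 0.66, 0.57, 1.07, 1.05, 1.02),
  stringsAsFactors = FALSE
)

element_mass <- function(element) {
  i <- match(element, .elements$element)
  if (anyNA(i)) {
    stop("unknown element(s): ", paste(unique(element[is.na(i)]), collapse = ", "))
  }
  .elements$mass[i]
}

covalent_radius <- function(element) {
  i <- match(element, .elements$element)
  if (anyNA(i)) {
    stop("unknown element(s): ", paste(unique(element[is.na(i)]), collapse = ", "))
  }
  .elements$r_cov[i]
}
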
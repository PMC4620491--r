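#' Physical constants and reference tables
#'
#' Unit conventions used throughout the package: coordinates in Angstrom,
#' switching-function radii in nm, energies in kJ/mol, temperatures in
#' Kelvin unless a function states otherwise.
#'
#' @name idpfel-constants
#' @keywords internal
NULL

## molar gas constant, kJ/(mol K)
.R_GAS <- 0.0083145

## Boltzmann constant, J/K
.KB_SI <- 1.380649e-23

## 1H gyromagnetic ratio, rad/(s T)
.GAMMA_1H <- 2.6752218744e8

## average residue masses, Da (amino acid minus one water)
.RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.WATER_MASS <- 18.0153

## one-letter -> three-letter residue codes
.AA3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", E = "GLU",
  Q = "GLN", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)
.AA1 <- stats::setNames(names(.AA3), .AA3)

## residues counted as hydrophobic for the coordination / similarity CVs
.HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W", "C")

## Bondi van der Waals radii by element, Angstrom
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80)
.VDW_DEFAULT <- 1.8

## dynamic viscosity of water, mPa s, at 0..100 degC (CRC handbook values)
.WATER_VISC_C <- seq(0, 100, by = 5)
.WATER_VISC_MPAS <- c(
  1.792, 1.519, 1.307, 1.138, 1.002, 0.8902, 0.7977, 0.7191, 0.6527,
  0.5958, 0.5465, 0.5036, 0.4660, 0.4329, 0.4035, 0.3774, 0.3540,
  0.3330, 0.3142, 0.2971, 0.2818
)

#' Thermal energy at a given temperature
#'
#' Returns kT in kJ/mol (molar convention, R*T). At the 350 K used for the
#' reference simulations this is 2.91 kJ/mol, i.e. the 2.9 kJ/mol quoted as
#' the scale of thermal fluctuations.
#'
#' @param temperature Temperature in K.
#' @return kT in kJ/mol.
#' @export
#' @examples
#' kT_at(350)
kT_at <- function(temperature) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  .R_GAS * temperature
}

#' Dynamic viscosity of water
#'
#' Linear interpolation of handbook values tabulated every 5 degC between
#' 0 and 100 degC.
#'
#' @param temperature_C Temperature in degrees Celsius.
#' @return Viscosity in Pa s.
#' @export
#' @examples
#' water_viscosity(25) # ~8.9e-4 Pa s
water_viscosity <- function(temperature_C) {
  stopifnot(is.numeric(temperature_C))
  if (any(temperature_C < 0 | temperature_C > 100))
    stop("water_viscosity is tabulated for 0-100 degC only")
  stats::approx(.WATER_VISC_C, .WATER_VISC_MPAS, xout = temperature_C)$y * 1e-3
}

## numerically stable log(sum(exp(x)))
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
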
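#' Average molecular mass of a peptide sequence
#'
#' Sum of average (not monoisotopic) residue masses plus one water.
#'
#' @param sequence One-letter amino-acid string or character vector.
#' @return Mass in Da.
#' @export
#' @examples
#' sequence_mass("G") # 75.07
sequence_mass <- function(sequence) {
  aa <- .split_sequence(sequence)
  if (length(aa) == 0L) stop("empty sequence")
  unknown <- setdiff(aa, names(.RESIDUE_MASS))
  if (length(unknown))
    stop("unknown residue code(s): ", paste(unique(unknown), collapse = ", "))
  sum(.RESIDUE_MASS[aa]) + .WATER_MASS
}

.split_sequence <- function(sequence) {
  if (length(sequence) == 1L)
    sequence <- strsplit(sequence, "")[[1]]
  as.character(sequence)
}

## empirical Rh coefficient sets. Mass basis: log10(Rh/A) = a + b log10(M/Da);
## length basis: Rh = a * N^b. Sources: SEC calibrations for folded/urea-
## unfolded/pre-molten-globule states and NMR-diffusion length scalings.
.RH_COEF <- list(
  mass = list(
    F   = c(a = -0.204, b = 0.357),
    U   = c(a = -0.649, b = 0.521),
    PMG = c(a = -0.210, b = 0.392)
  ),
  length = list(
    F = c(a = 4.75, b = 0.29),
    U = c(a = 2.21, b = 0.57)
  )
)

#' Empirical hydrodynamic radius of a polypeptide
#'
#' Predicts the hydrodynamic radius expected for a natively folded (`"F"`),
#' urea-unfolded (`"U"`) or pre-molten-globule (`"PMG"`) chain, either from
#' the molecular mass (log-linear relations) or from the number of residues
#' (power laws from NMR diffusion calibrations). The PMG state is only
#' calibrated on the mass basis.
#'
#' @param M Molecular mass in Da (mass basis).
#' @param N Number of residues (length basis).
#' @param state One of `"F"`, `"U"`, `"PMG"`.
#' @param basis `"mass"` or `"length"`; default picks whichever of `M`/`N`
#'   was supplied.
#' @return Rh in Angstrom.
#' @export
#' @examples
#' rh_empirical(N = 41, state = "F", basis = "length") # 13.9 A
#' rh_empirical(M = 4461, state = "PMG", basis = "mass") # ~17 A
rh_empirical <- function(M = NULL, N = NULL, state = c("F", "U", "PMG"),
                         basis = NULL) {
  state <- match.arg(state)
  if (is.null(basis))
    basis <- if (!is.null(M)) "mass" else "length"
  basis <- match.arg(basis, c("mass", "length"))
  cf <- .RH_COEF[[basis]][[state]]
  if (is.null(cf))
    stop("state ", state, " is not calibrated on the ", basis, " basis")
  if (basis == "mass") {
    if (is.null(M) || any(M <= 0)) stop("mass basis requires M > 0")
    unname(10^(cf["a"] + cf["b"] * log10(M)))
  } else {
    if (is.null(N) || any(N < 2)) stop("length basis requires N >= 2")
    unname(cf["a"] * N^cf["b"])
  }
}

#' Hydrodynamic radius from a SEC apparent molecular mass
#'
#' A protein eluting with apparent mass MMapp from a gel-filtration column
#' calibrated on folded standards has the hydrodynamic radius of a folded
#' protein of that mass, so the folded-state mass relation is applied to
#' MMapp directly.
#'
#' @param MMapp Apparent molecular mass in Da.
#' @return Rh in Angstrom.
#' @export
#' @examples
#' sec_rh_from_mmapp(8800) # ~16 A
sec_rh_from_mmapp <- function(MMapp) {
  stopifnot(all(MMapp > 0))
  rh_empirical(M = MMapp, state = "F", basis = "mass")
}

#' Compaction index
#'
#' Affine rescaling of a measured hydrodynamic radius between the unfolded
#' (CI = 0) and folded (CI = 1) reference radii. Values are not clamped;
#' results outside [0, 1] are flagged via the `"outside_range"` attribute.
#'
#' @param Rh Measured hydrodynamic radius, Angstrom.
#' @param Rh_U Unfolded-state reference radius, Angstrom.
#' @param Rh_F Folded-state reference radius, Angstrom.
#' @return Dimensionless compaction index.
#' @export
#' @examples
#' compaction_index(15.5, Rh_U = 18.0, Rh_F = 12.4) # 0.45
compaction_index <- function(Rh, Rh_U, Rh_F) {
  if (!(Rh_U > Rh_F && Rh_F > 0))
    stop("require Rh_U > Rh_F > 0")
  ci <- (Rh_U - Rh) / (Rh_U - Rh_F)
  attr(ci, "outside_range") <- any(ci < 0 | ci > 1)
  ci
}

#' Synthetic pulsed-field-gradient NMR diffusion decay
#'
#' Generates Stejskal-Tanner intensities
#' \eqn{I = I_0 \exp(-D\gamma^2 g^2 \delta^2 (\Delta - \delta/3))}
#' with optional multiplicative Gaussian noise; gamma is the 1H
#' gyromagnetic ratio.
#'
#' @param D Diffusion coefficient, m^2/s.
#' @param I0 Intensity at zero gradient (arbitrary units).
#' @param delta Gradient pulse duration, s.
#' @param Delta Diffusion time, s.
#' @param gradients Gradient strengths, T/m.
#' @param noise_sd Fractional standard deviation of multiplicative noise.
#' @param seed Integer seed.
#' @return An object of class `diffusion_decay` with fields `gradients`,
#'   `intensities`, `delta`, `Delta`, `gamma` and the ground-truth `D`.
#' @export
make_diffusion_decay <- function(D, I0 = 1, delta = 4e-3, Delta = 0.1,
                                 gradients = seq(0.025, 0.475, length.out = 16),
                                 noise_sd = 0, seed = 1) {
  stopifnot(D > 0, delta > 0, Delta > delta / 3, length(gradients) > 0)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(as.integer(seed))
  mu <- I0 * exp(-D * .GAMMA_1H^2 * gradients^2 * delta^2 * (Delta - delta / 3))
  eps <- if (noise_sd > 0) stats::rnorm(length(gradients), 0, noise_sd) else 0
  structure(
    list(gradients = gradients, intensities = mu * (1 + eps),
         delta = delta, Delta = Delta, gamma = .GAMMA_1H,
         true_D = D, true_I0 = I0),
    class = "diffusion_decay")
}

#' Fit a diffusion coefficient to a PFG-NMR decay
#'
#' Nonlinear least squares on the Stejskal-Tanner form, initialized from the
#' linearized fit of log intensity against squared gradient strength.
#'
#' @param decay A `diffusion_decay` object or a list with fields
#'   `gradients`, `intensities`, `delta`, `Delta` and optionally `gamma`.
#' @return List with `D` (m^2/s), `I0`, `residual_rms` and the `nls` fit.
#' @export
fit_diffusion <- function(decay) {
  g <- decay$gradients; I <- decay$intensities
  gamma <- if (!is.null(decay$gamma)) decay$gamma else .GAMMA_1H
  if (length(g) < 4 || length(unique(g)) < 3)
    stop("need at least 4 decay points at >= 3 distinct gradient strengths")
  if (any(I <= 0)) stop("intensities must be positive")
  if (any(diff(I[order(g)]) > 0))
    warning("intensities are not monotonically decreasing with gradient")
  b <- gamma^2 * decay$delta^2 * (decay$Delta - decay$delta / 3)
  lin <- stats::lm(log(I) ~ I(g^2))
  D0 <- max(-stats::coef(lin)[2] / b, 1e-14)
  ## fit D in units of 1e-10 m^2/s so the optimizer works on O(1)
  ## parameters; Levenberg-Marquardt copes with the zero-residual case
  df <- data.frame(g2 = g^2, I = I)
  fit <- minpack.lm::nlsLM(I ~ I0 * exp(-D10 * 1e-10 * b * g2), data = df,
                           start = list(I0 = unname(exp(stats::coef(lin)[1])),
                                        D10 = D0 / 1e-10))
  cf <- stats::coef(fit)
  list(D = unname(cf["D10"]) * 1e-10, I0 = unname(cf["I0"]),
       residual_rms = sqrt(mean(stats::resid(fit)^2)), fit = fit)
}

#' Hydrodynamic radius from the Stokes-Einstein relation
#'
#' @param D Diffusion coefficient, m^2/s.
#' @param T Temperature, K.
#' @param eta Solvent viscosity, Pa s (see [water_viscosity()]).
#' @return Rh in Angstrom.
#' @export
#' @examples
#' stokes_einstein_rh(1.545e-10, 298.15, water_viscosity(25)) # ~15.9 A
stokes_einstein_rh <- function(D, T, eta) {
  stopifnot(all(D > 0), all(T > 0), all(eta > 0))
  .KB_SI * T / (6 * pi * eta * D) * 1e10
}

#' Hydrodynamic radius via an internal diffusion standard
#'
#' Temperature and viscosity cancel in the ratio of diffusion coefficients,
#' so Rh of the sample follows from the reference compound's known radius.
#'
#' @param D_ref Reference diffusion coefficient, m^2/s.
#' @param D_sample Sample diffusion coefficient, m^2/s.
#' @param Rh_ref Reference hydrodynamic radius, Angstrom.
#' @return Rh of the sample, Angstrom.
#' @export
internal_standard_rh <- function(D_ref, D_sample, Rh_ref) {
  stopifnot(all(D_ref > 0), all(D_sample > 0), all(Rh_ref > 0))
  Rh_ref * D_ref / D_sample
}

#' Mean residue ellipticity of a CD spectrum
#'
#' MRE(lambda) = theta(lambda) * MRW / (10 l C), with the mean residue
#' weight MRW = m / (n_res - 1) (per peptide bond), theta in mdeg, path
#' length l in cm and concentration C in mg/mL.
#'
#' @param theta Raw ellipticity in mdeg (vector over wavelengths).
#' @param path_cm Path length, cm.
#' @param conc_mg_ml Protein concentration, mg/mL.
#' @param mass_da Molecular mass, Da.
#' @param n_res Number of residues.
#' @return MRE in deg cm^2/dmol, same length as `theta`.
#' @export
mean_residue_ellipticity <- function(theta, path_cm = 0.1, conc_mg_ml,
                                     mass_da, n_res) {
  stopifnot(path_cm > 0, mass_da > 0, n_res >= 2)
  if (conc_mg_ml <= 0) stop("concentration must be positive")
  mrw <- mass_da / (n_res - 1)
  theta * mrw / (10 * path_cm * conc_mg_ml)
}

#' Percent change relative to a reference condition
#'
#' @param x Values per condition.
#' @param ref Index or name of the reference condition.
#' @return Signed percent change per condition.
#' @export
#' @examples
#' percent_change(c(16.9, 15.5), ref = 1) # c(0, -8.3)
percent_change <- function(x, ref = 1) {
  x_ref <- x[[ref]]
  if (x_ref == 0) stop("reference value must be nonzero")
  100 * (x - x_ref) / x_ref
}

#' Check reversibility of a thermal transition
#'
#' Compares intensities measured on heating and on cooling over a shared
#' temperature grid.
#'
#' @param heating Named or plain numeric vector of intensities (heating leg).
#' @param cooling Same-length vector for the cooling leg.
#' @param tol Maximum tolerated relative deviation (default 0.1).
#' @return List with `reversible` (logical) and per-temperature `deviation`.
#' @export
reversibility_check <- function(heating, cooling, tol = 0.1) {
  if (length(heating) != length(cooling))
    stop("heating and cooling grids differ in length")
  if (!is.null(names(heating)) && !is.null(names(cooling)) &&
      !identical(names(heating), names(cooling)))
    stop("heating and cooling temperature grids differ")
  dev <- abs(cooling - heating) / abs(heating)
  list(reversible = max(dev) <= tol, deviation = dev)
}
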
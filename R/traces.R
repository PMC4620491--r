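#' Synthetic restrained force-field energy trace
#'
#' Emulates the energy series of a simulation restrained around a
#' microstate centroid: Gaussian total energies around a known mean, with a
#' prescribed fraction of frames violating the restraint (restraint energy
#' above the 2.9 kJ/mol thermal-fluctuation threshold) and carrying a +20
#' kJ/mol energy offset so that restraint filtering is detectable. Frames
#' are spaced 5 ps apart. Non-violating frames draw their restraint energy
#' uniformly below the threshold; violating frames exponentially above it.
#'
#' @param true_mean Ground-truth mean energy, kJ/mol.
#' @param sd Energy standard deviation, kJ/mol.
#' @param n_frames Number of frames.
#' @param restraint_violation_fraction Fraction of frames in violation
#'   (in [0, 1)).
#' @param seed Integer seed.
#' @return An object of class `energy_trace` with fields `frame_times`
#'   (ps), `total_energy`, `restraint_energy` and the generator-only
#'   `true_mean`.
#' @export
make_energy_trace <- function(true_mean, sd, n_frames,
                              restraint_violation_fraction = 0, seed = 1) {
  if (restraint_violation_fraction < 0 || restraint_violation_fraction >= 1)
    stop("restraint_violation_fraction must be in [0, 1)")
  stopifnot(sd >= 0, n_frames >= 1)
  set.seed(as.integer(seed))
  threshold <- 2.9
  e <- stats::rnorm(n_frames, true_mean, sd)
  violate <- stats::runif(n_frames) < restraint_violation_fraction
  r <- stats::runif(n_frames, 0, threshold)
  r[violate] <- threshold + stats::rexp(sum(violate), rate = 0.5)
  e[violate] <- e[violate] + 20
  structure(
    list(frame_times = 5 * seq_len(n_frames),
         total_energy = e, restraint_energy = r, true_mean = true_mean),
    class = "energy_trace")
}
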
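## Boltzmann weights over microstates with max-shift stabilization
.boltzmann_weights <- function(F, kT) {
  w <- exp(-(F - min(F)) / kT)
  w / sum(w)
}

#' Boltzmann-weighted ensemble average over microstates
#'
#' \deqn{\langle O \rangle = \sum_\alpha O_\alpha e^{-F_\alpha/kT} /
#'       \sum_\alpha e^{-F_\alpha/kT}}
#' with kT = R*T. `obs` holds one value (or one row of a vector-valued
#' observable) per microstate, in microstate order.
#'
#' @param fes A [reconstruct_fes()] result.
#' @param obs Numeric vector (one value per microstate) or matrix/
#'   data.frame (microstates x components).
#' @param T Temperature, K.
#' @return Scalar or per-component named vector.
#' @export
ensemble_average <- function(fes, obs, T = 350) {
  stopifnot(inherits(fes, "microstate_fes"), T > 0)
  F <- fes$microstates$F
  O <- if (is.data.frame(obs)) as.matrix(obs) else obs
  if (is.matrix(O)) {
    if (nrow(O) != length(F))
      stop("obs must have one row per microstate")
  } else {
    if (length(O) != length(F))
      stop("obs must have one value per microstate")
    O <- matrix(O, ncol = 1)
  }
  bad <- which(apply(O, 1, anyNA))
  if (length(bad))
    stop("observable missing for microstate(s): ",
         paste(fes$microstates$id[utils::head(bad, 5)], collapse = ", "))
  w <- .boltzmann_weights(F, kT_at(T))
  out <- colSums(w * O)
  if (ncol(O) == 1 && is.null(colnames(O))) unname(out) else out
}

#' Slice the landscape into free-energy bands
#'
#' Partitions the occupied microstates into half-open free-energy slices
#' \[i*width, (i+1)*width) from 0 up to the maximum F.
#'
#' @param fes A [reconstruct_fes()] result.
#' @param width Slice width, kJ/mol.
#' @return An object of class `fe_slices`: a list with `slices` (each with
#'   `lo`, `hi`, `members` = microstate row indices) and the `fes`.
#' @export
slice_landscape <- function(fes, width = 6) {
  stopifnot(inherits(fes, "microstate_fes"), width > 0)
  F <- fes$microstates$F
  idx <- pmin(floor(F / width), floor(max(F) / width))
  slices <- lapply(sort(unique(idx)), function(i)
    list(lo = i * width, hi = (i + 1) * width, members = which(idx == i)))
  structure(list(slices = slices, width = width, fes = fes),
            class = "fe_slices")
}

#' @export
print.fe_slices <- function(x, ...) {
  cat("fe_slices:", length(x$slices), "slices of width", x$width, "kJ/mol\n")
  for (s in x$slices)
    cat(sprintf("  [%g, %g): %d microstates\n", s$lo, s$hi, length(s$members)))
  invisible(x)
}

#' Per-microstate means of a per-frame observable
#'
#' Averages per-frame values (scalar or per-residue vectors) over the
#' member frames of each microstate; frames from all replicas pool
#' together with equal weight.
#'
#' @param occupancy A [assign_microstates()] result (also embedded in a
#'   `microstate_fes`).
#' @param values List, one element per replica, each a numeric vector or
#'   matrix with one row per retained frame of that replica.
#' @return Matrix microstates x components of per-microstate means O_alpha.
#' @export
microstate_observable <- function(occupancy, values) {
  if (inherits(occupancy, "microstate_fes")) occupancy <- occupancy$occupancy
  stopifnot(inherits(occupancy, "microstate_occupancy"),
            length(values) == length(occupancy$frames))
  vals <- lapply(values, function(v) if (is.matrix(v)) v else matrix(v, ncol = 1))
  for (k in seq_along(vals))
    if (nrow(vals[[k]]) != nrow(occupancy$frames[[k]]))
      stop("values for replica ", k, " must have one row per retained frame")
  V <- do.call(rbind, vals)
  bin <- unlist(occupancy$assign)
  n_bins <- nrow(occupancy$bins)
  out <- matrix(NA_real_, n_bins, ncol(V))
  for (j in seq_len(ncol(V)))
    out[, j] <- vapply(seq_len(n_bins), function(a) {
      sel <- bin == a
      if (any(sel)) mean(V[sel, j]) else NA_real_
    }, numeric(1))
  colnames(out) <- colnames(V)
  out
}

## within-slice microstate weights (Boltzmann renormalized, or uniform)
.slice_weights <- function(fes, members, weighting) {
  if (weighting == "uniform") rep(1 / length(members), length(members))
  else .boltzmann_weights(fes$microstates$F[members], fes$kT) /
    sum(.boltzmann_weights(fes$microstates$F[members], fes$kT))
}

#' Per-slice, per-residue secondary-structure populations
#'
#' Within each free-energy slice, the fraction of frames carrying each
#' label (H, E, P, C) is computed per residue, weighting microstates by
#' their Boltzmann weight renormalized within the slice (or uniformly).
#' Fractions sum to 1 per residue and slice.
#'
#' @param slices A [slice_landscape()] result.
#' @param per_frame_labels List, one element per replica, each a character
#'   matrix (retained frames x residues) of labels in `{H, E, P, C}`.
#' @param weighting `"boltzmann"` (default) or `"uniform"`.
#' @return Data.frame with columns `slice_lo`, `slice_hi`, `residue`,
#'   `H`, `E`, `P`, `C`.
#' @export
slice_ss_populations <- function(slices, per_frame_labels,
                                 weighting = c("boltzmann", "uniform")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(slices, "fe_slices"))
  fes <- slices$fes
  labels <- c("H", "E", "P", "C")
  ## per-microstate label fractions, one matrix per label
  fracs <- lapply(labels, function(L)
    microstate_observable(fes$occupancy, lapply(per_frame_labels, function(m)
      (m == L) * 1)))
  out <- list()
  for (s in slices$slices) {
    if (length(s$members) == 0L) next
    w <- .slice_weights(fes, s$members, weighting)
    row <- lapply(fracs, function(f)
      colSums(w * f[s$members, , drop = FALSE]))
    out[[length(out) + 1]] <- data.frame(
      slice_lo = s$lo, slice_hi = s$hi,
      residue = seq_along(row[[1]]),
      H = row[[1]], E = row[[2]], P = row[[3]], C = row[[4]])
  }
  do.call(rbind, out)
}

#' Per-slice, per-residue SASA difference from the global minimum
#'
#' For every slice, the weighted mean per-residue solvent-accessible
#' surface area minus that of the minimum-free-energy microstate; the
#' per-slice mean over residues is attached as attribute `"slice_mean"`.
#'
#' @param slices A [slice_landscape()] result.
#' @param per_frame_sasa List, one element per replica, each a numeric
#'   matrix (retained frames x residues) of per-residue SASA.
#' @param weighting `"boltzmann"` (default) or `"uniform"`.
#' @return Data.frame with `slice_lo`, `slice_hi`, `residue`,
#'   `delta_sasa`.
#' @export
slice_delta_sasa <- function(slices, per_frame_sasa,
                             weighting = c("boltzmann", "uniform")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(slices, "fe_slices"))
  fes <- slices$fes
  ms_sasa <- microstate_observable(fes$occupancy, per_frame_sasa)
  min_bin <- which.min(fes$microstates$F)
  if (is.na(ms_sasa[min_bin, 1]))
    stop("the global-minimum microstate has no member frames with SASA")
  ref <- ms_sasa[min_bin, ]
  out <- list(); means <- numeric(0)
  for (s in slices$slices) {
    if (length(s$members) == 0L) next
    w <- .slice_weights(fes, s$members, weighting)
    avg <- colSums(w * ms_sasa[s$members, , drop = FALSE])
    delta <- avg - ref
    out[[length(out) + 1]] <- data.frame(
      slice_lo = s$lo, slice_hi = s$hi,
      residue = seq_along(delta), delta_sasa = delta)
    means <- c(means, mean(delta))
  }
  res <- do.call(rbind, out)
  attr(res, "slice_mean") <- means
  res
}
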
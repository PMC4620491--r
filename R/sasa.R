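## deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area per residue
#'
#' Shrake-Rupley algorithm: each atom's accessible sphere (van der Waals
#' radius, Bondi set, plus probe radius) is covered with a deterministic
#' Fibonacci point lattice and the fraction of points not buried inside any
#' neighbouring atom's accessible sphere gives its area; areas are summed
#' per residue. Elements are inferred from atom names; unknown elements
#' get a 1.8 Angstrom radius with a warning.
#'
#' @param conf A [conformation()].
#' @param probe Probe radius, Angstrom (water: 1.4).
#' @param n_points Lattice points per atom sphere.
#' @return Numeric vector of per-residue SASA in Angstrom^2, with the
#'   molecular total as attribute `"total"`.
#' @export
#' @examples
#' pep <- make_toy_peptide(5, "CCCCC", seed = 1)
#' sasa <- sasa_per_residue(pep)
#' attr(sasa, "total")
sasa_per_residue <- function(conf, probe = 1.4, n_points = 960) {
  atoms <- conf$atoms
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  el <- .atom_element(atoms$elety)
  radii <- .VDW_RADII[el]
  if (anyNA(radii)) {
    warning("unknown element(s) ", paste(unique(el[is.na(radii)]), collapse = ", "),
            "; using ", .VDW_DEFAULT, " Angstrom")
    radii[is.na(radii)] <- .VDW_DEFAULT
  }
  radii <- unname(radii) + probe
  pts <- .fibonacci_sphere(n_points)
  n_atoms <- nrow(xyz)
  area <- numeric(n_atoms)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n_atoms)) {
    nb <- which(d2[i, ] < (radii[i] + radii)^2 & seq_len(n_atoms) != i)
    p <- sweep(pts * radii[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
             (p[, 3] - xyz[j, 3])^2
      free <- free & dj2 > radii[j]^2
    }
    area[i] <- 4 * pi * radii[i]^2 * mean(free)
  }
  out <- vapply(seq_along(conf$sequence),
                function(r) sum(area[atoms$resno == r]), numeric(1))
  names(out) <- seq_along(out)
  attr(out, "total") <- sum(area)
  out
}
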
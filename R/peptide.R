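## --- small 3-D geometry helpers -------------------------------------------

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit3 <- function(v) v / sqrt(sum(v^2))

## natural extension reference frame: place atom D given A-B-C, the bond
## length C-D, the bond angle B-C-D (deg) and the torsion A-B-C-D (deg)
.nerf <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- .unit3(c - b)
  n <- .unit3(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 Numeric xyz vectors.
#' @return Signed dihedral in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, .unit3(b2))
  -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

## --- conformation container -----------------------------------------------

#' Peptide conformation
#'
#' A light container for one peptide chain: a one-letter sequence and an
#' atom table with columns `resno`, `resid` (three-letter code), `elety`
#' (atom name) and Cartesian `x`, `y`, `z` in Angstrom. Every residue must
#' carry at least N, CA and C; residue numbering is contiguous from 1.
#'
#' @param sequence One-letter residue codes (string or vector).
#' @param atoms Atom data.frame as described above.
#' @param chain Chain identifier.
#' @return An object of class `conformation`.
#' @export
conformation <- function(sequence, atoms, chain = "A") {
  sequence <- .split_sequence(sequence)
  stopifnot(is.data.frame(atoms),
            all(c("resno", "resid", "elety", "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("coordinates must be finite")
  resnos <- sort(unique(atoms$resno))
  if (!identical(as.integer(resnos), seq_along(sequence)))
    stop("residue numbering must be contiguous 1..n and match the sequence")
  for (i in resnos) {
    present <- atoms$elety[atoms$resno == i]
    miss <- setdiff(c("N", "CA", "C"), present)
    if (length(miss))
      stop("residue ", i, " is missing backbone atom(s): ",
           paste(miss, collapse = ", "))
  }
  structure(list(sequence = sequence, atoms = atoms, chain = chain),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("conformation: %d residues, %d atoms (%s...)\n",
              length(x$sequence), nrow(x$atoms),
              paste(utils::head(x$sequence, 10), collapse = "")))
  invisible(x)
}

#' Coordinates of one named atom
#'
#' @param conf A [conformation()].
#' @param resno Residue number.
#' @param elety Atom name.
#' @return xyz vector, or `NULL` if absent.
#' @export
atom_xyz <- function(conf, resno, elety) {
  i <- which(conf$atoms$resno == resno & conf$atoms$elety == elety)
  if (length(i) == 0L) return(NULL)
  as.numeric(conf$atoms[i[1], c("x", "y", "z")])
}

#' Backbone phi/psi dihedrals
#'
#' @param conf A [conformation()].
#' @return Data.frame with `resno`, `phi`, `psi` in degrees (`NA` where the
#'   flanking residue is missing).
#' @export
backbone_dihedrals <- function(conf) {
  n <- length(conf$sequence)
  phi <- psi <- rep(NA_real_, n)
  xyz <- function(i, a) atom_xyz(conf, i, a)
  for (i in seq_len(n)) {
    if (i > 1)
      phi[i] <- dihedral_angle(xyz(i - 1, "C"), xyz(i, "N"),
                               xyz(i, "CA"), xyz(i, "C"))
    if (i < n)
      psi[i] <- dihedral_angle(xyz(i, "N"), xyz(i, "CA"),
                               xyz(i, "C"), xyz(i + 1, "N"))
  }
  data.frame(resno = seq_len(n), phi = phi, psi = psi)
}

## gamma heavy atom carried by each residue type (none for G and A)
.GAMMA_ATOM <- c(
  R = "CG", N = "CG", D = "CG", C = "SG", E = "CG", Q = "CG", H = "CG",
  I = "CG1", L = "CG", K = "CG", M = "CG", F = "CG", P = "CG", S = "OG",
  T = "OG1", W = "CG", Y = "CG", V = "CG1"
)

## ideal backbone geometry (Engh-Huber-like averages), Angstrom / degrees
.GEO <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.53,
  cb_g = 1.52, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, ang_n_ca_cb = 110.5, ang_ca_cb_g = 114.0,
  tor_cb = -122.6, omega = 180
)

#' Build a toy peptide with prescribed secondary structure
#'
#' Constructs backbone coordinates (N, CA, C, O, plus CB and a single gamma
#' heavy atom where the residue type has one) from ideal bond geometry and
#' per-residue dihedrals: helix `H` uses (phi, psi) = (-57, -47), strand
#' `E` (-139, 135), and coil `C` draws from the broad beta/PPII basin
#' (phi in \[-150, -60\], psi in \[90, 180\]) with a 20% admixture of the
#' alpha basin. Self-clashing coil draws (non-neighbour atoms closer than
#' 1.5 Angstrom) are rejected and resampled.
#'
#' @param n_res Number of residues (>= 3).
#' @param ss_string Secondary-structure string over `{H, E, C}`, one char
#'   per residue.
#' @param seed Integer seed.
#' @param sequence Optional one-letter sequence (default poly-alanine).
#' @param chi1 Optional side-chain chi1 torsion(s) in degrees (recycled);
#'   default draws from the -60/60/180 rotamers.
#' @return A [conformation()].
#' @export
#' @examples
#' helix <- make_toy_peptide(12, strrep("H", 12), seed = 1)
make_toy_peptide <- function(n_res, ss_string, seed = 1, sequence = NULL,
                             chi1 = NULL) {
  if (n_res < 3) stop("n_res must be at least 3")
  ss <- strsplit(ss_string, "")[[1]]
  if (length(ss) != n_res)
    stop("ss_string length must equal n_res")
  if (!all(ss %in% c("H", "E", "C")))
    stop("ss_string may only contain H, E or C")
  if (is.null(sequence)) sequence <- rep("A", n_res)
  sequence <- .split_sequence(sequence)
  if (length(sequence) != n_res) stop("sequence length must equal n_res")
  set.seed(as.integer(seed))
  if (!is.null(chi1)) chi1 <- rep_len(chi1, n_res)

  draw_dihedrals <- function() {
    phi <- psi <- numeric(n_res)
    for (i in seq_len(n_res)) {
      if (ss[i] == "H") { phi[i] <- -57; psi[i] <- -47 }
      else if (ss[i] == "E") { phi[i] <- -139; psi[i] <- 135 }
      else if (stats::runif(1) < 0.8) {
        phi[i] <- stats::runif(1, -150, -60); psi[i] <- stats::runif(1, 90, 180)
      } else {
        phi[i] <- stats::runif(1, -100, -30); psi[i] <- stats::runif(1, -67, -7)
      }
    }
    list(phi = phi, psi = psi)
  }

  build <- function(phi, psi) {
    g <- .GEO
    N <- CA <- C <- O <- vector("list", n_res)
    N[[1]] <- c(0, 0, 0)
    CA[[1]] <- c(g$n_ca, 0, 0)
    th <- (180 - g$ang_n_ca_c) * pi / 180
    C[[1]] <- CA[[1]] + g$ca_c * c(cos(th), sin(th), 0)
    for (i in 2:n_res) {
      N[[i]] <- .nerf(N[[i - 1]], CA[[i - 1]], C[[i - 1]], g$c_n,
                      g$ang_ca_c_n, psi[i - 1])
      CA[[i]] <- .nerf(CA[[i - 1]], C[[i - 1]], N[[i]], g$n_ca,
                       g$ang_c_n_ca, g$omega)
      C[[i]] <- .nerf(C[[i - 1]], N[[i]], CA[[i]], g$ca_c,
                      g$ang_n_ca_c, phi[i])
    }
    rows <- list()
    for (i in seq_len(n_res)) {
      O[[i]] <- .nerf(N[[i]], CA[[i]], C[[i]], g$c_o, g$ang_ca_c_o,
                      psi[i] + 180)
      res3 <- .AA3[[sequence[i]]]
      add <- function(name, p)
        data.frame(resno = i, resid = res3, elety = name,
                   x = p[1], y = p[2], z = p[3])
      rows[[length(rows) + 1]] <- add("N", N[[i]])
      rows[[length(rows) + 1]] <- add("CA", CA[[i]])
      rows[[length(rows) + 1]] <- add("C", C[[i]])
      rows[[length(rows) + 1]] <- add("O", O[[i]])
      if (sequence[i] != "G") {
        CB <- .nerf(C[[i]], N[[i]], CA[[i]], g$ca_cb, g$ang_n_ca_cb, g$tor_cb)
        rows[[length(rows) + 1]] <- add("CB", CB)
        gname <- .GAMMA_ATOM[sequence[i]]
        if (!is.na(gname)) {
          x1 <- if (!is.null(chi1)) chi1[i]
                else sample(c(-60, 60, 180), 1) + stats::rnorm(1, 0, 8)
          G <- .nerf(N[[i]], CA[[i]], CB, g$cb_g, g$ang_ca_cb_g, x1)
          rows[[length(rows) + 1]] <- add(unname(gname), G)
        }
      }
    }
    do.call(rbind, rows)
  }

  has_clash <- function(atoms) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    resno <- atoms$resno
    dm <- as.matrix(stats::dist(xyz))
    sep <- abs(outer(resno, resno, "-"))
    any(dm[sep >= 2] < 1.5)
  }

  dh <- draw_dihedrals()
  atoms <- build(dh$phi, dh$psi)
  tries <- 0
  while (any(ss == "C") && has_clash(atoms) && tries < 30) {
    dh <- draw_dihedrals()
    atoms <- build(dh$phi, dh$psi)
    tries <- tries + 1
  }
  if (tries >= 30 && has_clash(atoms))
    warning("clash rejection exhausted 30 attempts; returning last draw")
  conf <- conformation(sequence, atoms)
  attr(conf, "phi") <- dh$phi
  attr(conf, "psi") <- dh$psi
  conf
}
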
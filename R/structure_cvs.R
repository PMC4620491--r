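#' Switching-function parameters
#'
#' Rational switching function used by the contact-like collective
#' variables: s(r) = (1 - x^n)/(1 - x^m) with x = (r - d0)/r0 and m > n.
#' Radii are in nm.
#'
#' @param n Numerator exponent.
#' @param m Denominator exponent.
#' @param r0 Reference radius, nm.
#' @param d0 Offset, nm.
#' @return An object of class `switching_params`.
#' @export
switching_params <- function(n = 4, m = 8, r0 = 0.4, d0 = 0) {
  stopifnot(m > n, n > 0, r0 > 0, d0 >= 0)
  structure(list(n = n, m = m, r0 = r0, d0 = d0), class = "switching_params")
}

#' Rational switching function
#'
#' Monotone non-increasing map of a distance to (0, 1]: 1 at r = d0,
#' n/m at r = d0 + r0 (the removable singularity is handled by the
#' L'Hopital limit), decaying as x^(n-m) at large r. Distances below d0
#' clamp to 1.
#'
#' @param r Distance(s), nm.
#' @param p A [switching_params()].
#' @return Switching value(s) in (0, 1].
#' @export
#' @examples
#' switching(0.4, switching_params(4, 8, r0 = 0.4)) # 0.5
switching <- function(r, p = switching_params()) {
  stopifnot(inherits(p, "switching_params"), all(r >= 0))
  x <- pmax((r - p$d0) / p$r0, 0)
  out <- numeric(length(x))
  near1 <- abs(x - 1) < 1e-8
  out[near1] <- p$n / p$m
  xi <- x[!near1]
  out[!near1] <- (1 - xi^p$n) / (1 - xi^p$m)
  out
}

## side-chain reference atom: CB, falling back to CA for glycine (or, with
## a warning, for residues missing CB)
.sc_ref_xyz <- function(conf, resno) {
  p <- atom_xyz(conf, resno, "CB")
  if (is.null(p)) {
    if (conf$sequence[resno] != "G")
      warning("residue ", resno, " has no CB; using CA")
    p <- atom_xyz(conf, resno, "CA")
  }
  p
}

#' Side-chain coordination number
#'
#' Sum of the switching function over all distinct pairs of side-chain
#' reference atoms (CB, or CA for glycine) within a residue selection;
#' same-residue pairs are excluded. Defaults to the hydrophobic residues
#' with contact parameters n = 4, m = 8, R0 = 0.4 nm.
#'
#' @param conf A [conformation()].
#' @param residue_set Residue numbers to include; default all hydrophobic
#'   residues (A, V, L, I, M, F, W, C).
#' @param p A [switching_params()].
#' @return Dimensionless coordination number.
#' @export
coordination_number <- function(conf, residue_set = NULL,
                                p = switching_params(4, 8, r0 = 0.4)) {
  if (is.null(residue_set))
    residue_set <- which(conf$sequence %in% .HYDROPHOBIC)
  if (length(residue_set) == 0L) stop("empty residue selection")
  if (length(residue_set) == 1L) return(0)
  xyz <- t(vapply(residue_set, function(i) .sc_ref_xyz(conf, i), numeric(3)))
  dmat <- as.matrix(stats::dist(xyz)) / 10  # Angstrom -> nm
  sum(switching(dmat[upper.tri(dmat)], p))
}

## atoms used for segment RMSD (CB included when both have it)
.SEG_ATOMS <- c("N", "CA", "C", "O", "CB")

## xyz matrix of the segment's N/CA/C/O/CB atoms, rows named by
## "<position-in-segment> <atom>"; atoms a residue lacks are absent
.segment_xyz <- function(conf, residues, atoms = .SEG_ATOMS) {
  out <- list()
  for (k in seq_along(residues))
    for (a in atoms) {
      p <- atom_xyz(conf, residues[k], a)
      if (!is.null(p)) out[[paste(k, a)]] <- p
    }
  do.call(rbind, out)
}

## ideal 6-residue helix template and 3+3-residue beta-pair templates,
## built once from the ideal-geometry backbone builder
.cv_templates <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    helix <- make_toy_peptide(6, "HHHHHH", seed = 1)
    strand <- make_toy_peptide(3, "EEE", seed = 1)
    s1 <- .segment_xyz(strand, 1:3)
    s1 <- sweep(s1, 2, colMeans(s1))
    ## antiparallel partner: pi rotation about the z axis (reverses the
    ## strand direction), offset 4.8 A along z (the H-bond direction);
    ## parallel partner: plain 4.8 A offset
    Rz <- matrix(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), 3, 3)
    off <- c(0, 0, 4.8)
    pair <- function(s2) {
      m <- rbind(s1, s2)
      rownames(m) <- c(paste("a", rownames(s1)), paste("b", rownames(s1)))
      m
    }
    cache <<- list(
      helix = .segment_xyz(helix, 1:6),
      anti = pair(sweep(s1 %*% t(Rz), 2, off, "+")),
      para = pair(sweep(s1, 2, off, "+")))
    cache
  }
})

## least-RMSD (Kabsch) superposition distance, returns Angstrom
.fit_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  s <- svd(crossprod(B, A))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((A - B %*% R)^2)))
}

#' Secondary-structure segment count CV
#'
#' Sums the switching function of the backbone RMSD (nm) between candidate
#' segments and an internal ideal template. For `alpha`, candidates are all
#' contiguous 6-residue windows against an ideal helix. For `antibeta` /
#' `parabeta`, candidates are pairs of 3-residue segments, at least 2
#' residues apart in sequence and at most `max_sep` apart, against an
#' ideal anti-parallel / parallel strand pair. RMSD uses N, CA, C, O, CB
#' after optimal superposition. Default switching parameters follow the
#' biasing setup: (n=4, m=8, R0=0.1 nm) for alpha, (n=6, m=12, R0=0.1 nm)
#' for the beta modes.
#'
#' @param conf A [conformation()].
#' @param mode `"alpha"`, `"antibeta"` or `"parabeta"`.
#' @param p A [switching_params()]; mode-specific default.
#' @param max_sep Maximum start-index separation of beta segment pairs.
#' @return Dimensionless window/pair count.
#' @export
ss_segment_count <- function(conf, mode = c("alpha", "antibeta", "parabeta"),
                             p = NULL, max_sep = 30) {
  mode <- match.arg(mode)
  n <- length(conf$sequence)
  if (n < 6) {
    warning("fewer than 6 residues; segment count is 0")
    return(0)
  }
  if (is.null(p))
    p <- if (mode == "alpha") switching_params(4, 8, r0 = 0.1)
         else switching_params(6, 12, r0 = 0.1)
  tmpl <- .cv_templates()
  total <- 0
  rmsd_to <- function(win, ref) {
    ## align by row name so residues lacking CB (glycine) just drop out
    common <- intersect(rownames(win), rownames(ref))
    .fit_rmsd(win[common, , drop = FALSE], ref[common, , drop = FALSE])
  }
  if (mode == "alpha") {
    ref <- tmpl$helix
    for (i in seq_len(n - 5)) {
      win <- .segment_xyz(conf, i:(i + 5))
      total <- total + switching(rmsd_to(win, ref) / 10, p)
    }
  } else {
    ref <- if (mode == "antibeta") tmpl$anti else tmpl$para
    starts <- seq_len(n - 2)
    seg_cache <- lapply(starts, function(i) .segment_xyz(conf, i:(i + 2)))
    for (i in starts) {
      jmax <- min(i + max_sep, n - 2)
      js <- starts[starts >= i + 5 & starts <= jmax]
      for (j in js) {
        seg <- rbind(seg_cache[[i]], seg_cache[[j]])
        rownames(seg) <- c(paste("a", rownames(seg_cache[[i]])),
                           paste("b", rownames(seg_cache[[j]])))
        total <- total + switching(rmsd_to(seg, ref) / 10, p)
      }
    }
  }
  total
}

#' Side-chain chi1 dihedral
#'
#' N-CA-CB-gamma torsion; `NA` when the residue lacks the needed atoms.
#'
#' @param conf A [conformation()].
#' @param resno Residue number.
#' @return chi1 in degrees or `NA`.
#' @export
chi1_angle <- function(conf, resno) {
  gname <- .GAMMA_ATOM[conf$sequence[resno]]
  if (is.na(gname)) return(NA_real_)
  pN <- atom_xyz(conf, resno, "N"); pCA <- atom_xyz(conf, resno, "CA")
  pCB <- atom_xyz(conf, resno, "CB"); pG <- atom_xyz(conf, resno, gname)
  if (is.null(pCB) || is.null(pG)) return(NA_real_)
  dihedral_angle(pN, pCA, pCB, pG)
}

#' Side-chain dihedral similarity CV
#'
#' 0.5 * sum over counted residues of (1 + cos(chi1 - reference)); counts
#' residues of the requested class that have a defined chi1. Residues
#' without the needed side-chain atoms are skipped.
#'
#' @param conf A [conformation()].
#' @param reference_angles Named (by residue number) or positional vector
#'   of reference chi1 angles, degrees; must cover every counted residue.
#' @param class `"hydrophobic"` or `"polar"`.
#' @return Dimensionless similarity in \[0, n_counted\].
#' @export
alphabeta_similarity <- function(conf, reference_angles,
                                 class = c("hydrophobic", "polar")) {
  class <- match.arg(class)
  in_class <- if (class == "hydrophobic") conf$sequence %in% .HYDROPHOBIC
              else !(conf$sequence %in% .HYDROPHOBIC)
  idx <- which(in_class)
  chi <- vapply(idx, function(i) chi1_angle(conf, i), numeric(1))
  idx <- idx[!is.na(chi)]; chi <- chi[!is.na(chi)]
  if (length(idx) == 0L) return(0)
  ref <- if (!is.null(names(reference_angles)))
    as.numeric(reference_angles[as.character(idx)])
  else rep_len(as.numeric(reference_angles), length(conf$sequence))[idx]
  if (any(is.na(ref)))
    stop("reference angle missing for residue(s): ",
         paste(idx[is.na(ref)], collapse = ", "))
  0.5 * sum(1 + cos((chi - ref) * pi / 180))
}

#' Dihedral-region secondary-structure assignment
#'
#' Assigns each residue one label: `H` (helical: phi in \[-100, -30\], psi
#' in \[-67, -7\], in runs of >= 4), `E` (extended/strand: phi in
#' \[-180, -90\], psi in \[90, 180\], runs of >= 2), `P` (polyproline II:
#' phi in \[-90, -55\], psi in \[120, 180\], if not already strand) or `C`
#' (coil). Terminal residues without both dihedrals, and runs interrupted
#' by a chain break (consecutive CA further than 4.5 Angstrom), default
#' to coil.
#'
#' @param conf A [conformation()].
#' @return Character vector of per-residue labels in `{H, E, P, C}`.
#' @export
assign_secondary_structure <- function(conf) {
  n <- length(conf$sequence)
  dh <- backbone_dihedrals(conf)
  lab <- rep("C", n)
  ## chain breaks split runs
  ca <- t(vapply(seq_len(n), function(i) atom_xyz(conf, i, "CA"), numeric(3)))
  brk <- c(FALSE, sqrt(rowSums(diff(ca)^2)) > 4.5)  # brk[i]: break before i
  inbox <- function(lo_phi, hi_phi, lo_psi, hi_psi)
    !is.na(dh$phi) & !is.na(dh$psi) &
      dh$phi >= lo_phi & dh$phi <= hi_phi &
      dh$psi >= lo_psi & dh$psi <= hi_psi
  assign_runs <- function(ok, min_run, label, only_if = rep(TRUE, n)) {
    i <- 1
    while (i <= n) {
      if (ok[i]) {
        j <- i
        while (j < n && ok[j + 1] && !brk[j + 1]) j <- j + 1
        if (j - i + 1 >= min_run) {
          sel <- i:j
          lab[sel[only_if[sel]]] <<- label
        }
        i <- j + 1
      } else i <- i + 1
    }
  }
  assign_runs(inbox(-180, -90, 90, 180), 2, "E")
  assign_runs(inbox(-90, -55, 120, 180), 1, "P", only_if = lab != "E")
  assign_runs(inbox(-100, -30, -67, -7), 4, "H")
  lab
}

## element inferred from the atom name's leading letter
.atom_element <- function(elety) {
  el <- substr(gsub("^[0-9]+", "", elety), 1, 1)
  el
}

.ATOM_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)

#' Radius of gyration
#'
#' sqrt(sum w_i |x_i - xbar|^2 / sum w_i) over all atoms, optionally
#' mass-weighted by element.
#'
#' @param conf A [conformation()].
#' @param mass_weighted Use atomic masses as weights.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(conf, mass_weighted = FALSE) {
  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")])
  if (nrow(xyz) < 2) stop("need at least 2 atoms")
  w <- if (mass_weighted) {
    m <- .ATOM_MASS[.atom_element(conf$atoms$elety)]
    m[is.na(m)] <- 12
    m
  } else rep(1, nrow(xyz))
  ctr <- colSums(xyz * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)) / sum(w))
}
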
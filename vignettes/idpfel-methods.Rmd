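---
title: "Reconstructing disordered-peptide free-energy landscapes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing disordered-peptide free-energy landscapes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpfel)
```

## The problem

Intrinsically disordered peptides such as the 40-residue amyloid-beta
fragment have no single native structure: their global free-energy minimum
is an ensemble of expanded, largely coil-like conformations, while
partially structured conformations (helical or beta-rich) sit only a few
kJ/mol higher. A consequence of this *inverted* landscape is that heating
populates the more structured, more compact states — the opposite of
thermal unfolding in globular proteins.

`idpfel` implements the computational machinery needed to quantify this
picture from bias-exchange metadynamics data and from the accompanying
bench experiments:

1. reconstruction of microstate free energies from biased collective
   variable (CV) trajectories (`assign_microstates()`,
   `reconstruct_fes()`, `estimate_errors()`, `refine_bins()`);
2. Boltzmann-weighted ensemble observables and free-energy-sliced
   summaries (`ensemble_average()`, `slice_landscape()`,
   `slice_ss_populations()`, `slice_delta_sasa()`);
3. structural CVs and observables from conformations
   (`coordination_number()`, `ss_segment_count()`,
   `assign_secondary_structure()`, `sasa_per_residue()`,
   `radius_of_gyration()`);
4. a two-state Gibbs–Helmholtz model of temperature-induced structuring
   (`two_state()`, `delta_g_of_T()`, `t_max_structured()`);
5. hydrodynamic and spectroscopic analysis (`rh_empirical()`,
   `compaction_index()`, `fit_diffusion()`, `stokes_einstein_rh()`,
   `mean_residue_ellipticity()`);
6. synthetic-data generators with exact ground truth
   (`make_landscape()`, `sample_biased_replicas()`, `make_toy_peptide()`,
   `make_diffusion_decay()`, `make_energy_trace()`).

## Free-energy reconstruction

### Microstates

CV space is divided into axis-aligned hypercubes; every post-equilibration
frame (time > `t_eq`) of every replica falls into exactly one. The default
bin width per CV equals the Gaussian width used to bias that CV, the
natural resolution of the bias. A hypercube is a *proper* microstate only
if its members are structurally consistent; `refine_bins()` measures the
member spread in every trajectory CV not used for binning and recursively
halves offending bins along their widest binned axis, down to 1/8 of the
original width.

### The weighted-histogram equations

Each replica k contributes occupancies $n_{k\alpha}$ collected under its
one-dimensional bias $V_k$ (evaluated at the microstate center along the
CV that replica biases). The free energies solve the standard
self-consistent multi-histogram system

$$F_\alpha = -kT\,\ln\frac{\sum_k n_{k\alpha}}
      {\sum_k N_k\, e^{(f_k - V_k(s_\alpha))/kT}},\qquad
  f_k = -kT \ln \sum_\alpha e^{-(F_\alpha + V_k(s_\alpha))/kT},$$

iterated from $f_k = 0$ until the largest change in any $F_\alpha$ falls
below `tol` (default $10^{-4}$ kJ/mol), then shifted so the global minimum
is zero. All sums are evaluated in log space with max-shift, so bias
magnitudes of hundreds of kJ/mol are unproblematic. For a single replica
the equations collapse to the closed-form reweighting
$F_\alpha = -kT \ln n_\alpha - V(s_\alpha) + \mathrm{const}$, which the
test suite uses as an independent oracle; with zero bias they reduce to
the histogram estimator. Adding a constant to any bias changes nothing
(gauge invariance).

Two assumptions matter. First, the bias must be quasi-stationary after
`t_eq`; the package uses the time *average* of the accumulated bias over
the post-`t_eq` window as $V_k$, which suppresses the residual oscillation
of a non-tempered bias (the final instantaneous grid is kept as an
attribute). Second, each replica's biased CV must be one of the binning
CVs, otherwise $V_k(s_\alpha)$ is undefined and the reconstruction stops
with an error.

### Errors

`estimate_errors()` recomputes the WHAM solution on `n_blocks` (default 4)
contiguous time blocks and reports the standard deviation over blocks
divided by $\sqrt{n_\text{blocks}}$. Because each block's free energies
carry their own arbitrary offset, blocks are aligned at the full-estimate
global-minimum microstate (falling back to min-zero if a block never
visits it). A microstate absent from any block gets `NA` — an honest
"unavailable", never a spurious zero.

## The synthetic bias-exchange generator

The generator defaults are the standard conditions of a peptide
bias-exchange run: Gaussians of height 0.30 kJ/mol deposited every 5 ps,
bias exchanges every 20 ps, loose upper walls, kT = 2.9 kJ/mol (350 K),
and an equilibration time of roughly half the run. One sampler step stands in for 1 ps, so the
deposition and exchange strides keep their familiar values of 5 and 20.

`make_landscape()` defines the ground truth as a Boltzmann softmin of
parabolic basins,
$F(s) = -kT\ln\sum_w \exp\{-[-d_w + \sum_j ((s_j-c_{wj})/\sigma_{wj})^2]/kT\}$,
normalized to zero at its global minimum; exact marginals come from dense
quadrature (`landscape_marginal()`). `sample_biased_replicas()` runs one
Metropolis walker per replica on $F + V_k + V_\text{wall}$. Any ergodic
sampler of that density validates the estimator equally well — atomistic
dynamics is *not* being simulated, which is also why force fields, water,
and realistic time scales are out of scope. The proposal width is tuned to
a 30–50% acceptance rate during burn-in. Walls are half-harmonic,
$\tfrac12 \kappa (s-s_\text{wall})^2$ above the wall position, with
$\kappa = 500$ kJ/mol per CV-unit² — the standard metadynamics wall form;
positions are configurable because "loose upper boundaries" fixes no
number.

One numerical subtlety deserves its own paragraph. On a finite CV domain,
depositing plain Gaussians lets kernel mass fall off the grid near a hard
boundary; the bias there lags, a dip forms at the edge, walkers accumulate
in the dip and deepen it further. The artifact grows with simulation
length and eventually plants spurious deep microstates in the domain
corners. The deposition kernel is therefore *reflected* at the domain
boundaries (mirror images at $2\,\text{lo}-c$ and $2\,\text{hi}-c$), which
restores a uniform deposition rate near the edges. With this kernel the
two-replica, 80 000-step runs used in the tests recover a three-well
two-CV landscape with a median absolute error of about 0.5 kJ/mol for
microstates below 40 kJ/mol — comfortably within the 2–3 kJ/mol precision
that block analysis attributes to the bias potentials themselves.

Problem sizes in the tests and the acceptance script — two replicas,
80 000 steps, `t_eq` = 40 000, ~600 occupied microstates — were chosen as
the smallest setting at which the bias is visibly stationary over the
measurement window; they run in seconds.

## Structural collective variables

* **Switching function.** $s(r) = (1-x^n)/(1-x^m)$, $x = (r-d_0)/r_0$,
  with the removable singularity at $x = 1$ evaluated as $n/m$. Radii are
  in nm (coordinates elsewhere are in Å; the conversion is explicit).
  Parameter sets follow the biasing setup: contacts $(n,m,r_0) =
  (4,8,0.4)$, helix windows $(4,8,0.1)$, sheet pairs $(6,12,0.1)$.
* **Coordination number.** Switching summed over distinct pairs of
  side-chain reference atoms (CB, CA for glycine) of the hydrophobic
  residues by default.
* **Segment counts.** Helix: all 6-residue windows scored by backbone
  RMSD (N, CA, C, O, CB after optimal superposition) against an ideal
  helix template built internally from ideal dihedrals (−57°, −47°).
  Sheet: pairs of 3-residue segments, at least two residues apart and at
  most 30 apart (configurable cost cap), against ideal anti-parallel /
  parallel pair templates. The templates are this package's own — built
  from the same ideal-geometry backbone constructor — because the upstream
  CV implementation inherits its templates from simulation software
  without printing them; what matters, and what the tests pin down, is
  near-zero RMSD on ideal fixtures and clear separation between classes.
* **Dihedral similarity.** $\tfrac12\sum_i [1 + \cos(\chi_{1,i} -
  \text{ref}_i)]$ over the hydrophobic or polar residue class; χ1 is the
  side-chain dihedral used, and reference angles are caller-supplied
  because no published table exists for them.
* **Secondary-structure labels.** A dihedral-region rule: helix
  φ ∈ [−100°, −30°], ψ ∈ [−67°, −7°] in runs of ≥ 4; strand φ ∈ [−180°,
  −90°], ψ ∈ [90°, 180°] in runs of ≥ 2; polyproline II φ ∈ [−90°, −55°],
  ψ ∈ [120°, 180°] when not already strand; coil otherwise, with chain
  breaks (CA–CA > 4.5 Å) splitting runs and termini defaulting to coil.
  This is a deliberate, stated approximation to hydrogen-bond-based
  assignment (DSSP-class methods): dihedral boxes misclassify isolated
  bridge residues and PPII boundaries, but they are exact on the ideal
  fixtures the generator produces and fast enough for per-frame labels.
* **SASA.** Shrake–Rupley with a deterministic Fibonacci sphere lattice
  (960 points/atom), Bondi radii, 1.4 Å probe. Doubling the lattice
  changes totals by < 0.5%; an isolated atom reproduces
  $4\pi(r+r_p)^2$ to 1%.

The toy-peptide builder places N, CA, C, O, CB (and one gamma heavy atom
where the residue type has one) by natural-extension-reference-frame
geometry with ideal bond lengths and angles, exact user-specified
backbone dihedrals, and verified L-chirality (the C–N–CA–CB improper is
−122.6°, matching real structures). Coil residues draw φ/ψ from the broad
beta/PPII basin with a 20% alpha-basin admixture — enough to *look*
disordered; it is not a statistical model of real coil ensembles.

## The two-state thermal model

For a structured state S against the unstructured reference U, with
$\Delta S(T_\text{ref}) = (\Delta H - \Delta G)/T_\text{ref}$ derived from
the known free energy, constant-$\Delta C_p$ Gibbs–Helmholtz gives

$$\Delta G(T) = \Delta H_\text{ref} - T\,\Delta S_\text{ref}
 + \Delta C_p\left[(T - T_\text{ref}) - T \ln(T/T_\text{ref})\right].$$

The heat-capacity difference is stored in the *structuring* (U→S)
direction, hence negative (−1.98 kJ mol⁻¹ K⁻¹ for the packaged example):
only that sign yields a finite-temperature maximum of the structured
population below the reference temperature. The log population ratio
$-\Delta G/(RT)$ is maximal where $\Delta H(T) = 0$, i.e.
$T^* = T_\text{ref} - \Delta H_\text{ref}/\Delta C_p$; the implementation
cross-checks the closed form against a grid search, and uses $R\,T$ (not a
fixed kT) in the ratio. For the packaged beta-rich and helix-rich example
states, $T^*$ is 319.7 K and 335.9 K. Restraint-filtered enthalpies
(`estimate_enthalpy()`) discard frames whose restraint energy exceeds the
thermal fluctuation scale (2.9 kJ/mol) and include the restraint term in
the averaged energy.

## The biophysics layer

The empirical hydrodynamic-radius relations are log-linear in mass —
$\log_{10} R_h = a + b \log_{10} M$ with $(a,b)$ = (−0.204, 0.357) folded,
(−0.649, 0.521) urea-unfolded, (−0.21, 0.392) pre-molten globule — or
power laws in chain length, $4.75\,N^{0.29}$ (folded) and $2.21\,N^{0.57}$
(unfolded). The sources print these equations only by citation; the
coefficient sets shipped here are the published calibrations that
reproduce the reference radii used throughout (13.9 / 18.4 Å at N = 41;
17 Å for a 4461 Da pre-molten globule; 16 Å from an 8.8 kDa apparent
mass). They live in a single editable table. The compaction index
$(R_{h,U} - R_h)/(R_{h,U} - R_{h,F})$ is affine and unclamped, with
out-of-range values flagged. One known discrepancy is documented rather
than fitted away: with the reference radii 18.0/12.4 Å the 5 °C value
computes to 0.20, while the published table rounds it to 0.21.

PFG-NMR decays follow Stejskal–Tanner,
$I = I_0 e^{-D\gamma^2 g^2\delta^2(\Delta-\delta/3)}$; fitting uses a
linearized initializer and Levenberg–Marquardt (which also handles the
zero-residual noiseless case). Stokes–Einstein converts D to $R_h$ with a
tabulated water-viscosity curve; in practice the internal-standard route
$R_h = R_{h,\text{ref}}\, D_\text{ref}/D$ is preferred since temperature
and viscosity cancel. Mean residue ellipticity uses the mean residue
weight per peptide bond, MRW = m/(n_res − 1) — the convention under which
the printed path length, mass and concentration give magnitudes in the
usual 10⁴ deg cm² dmol⁻¹ range.

## What passing tests do and do not show

The generators reproduce the *statistical* structure the estimators rely
on: known multi-basin free energies, biased sampling under 1-D bias
potentials with exchanges, exponential decays with known D, energy traces
with a restraint channel. They do not reproduce atomistic kinetics,
solvent effects, CV cross-correlations of a real peptide, spectrometer
baselines, or aggregation. Recovery of a known landscape to ~0.5 kJ/mol
therefore validates the estimator chain, not the force-field accuracy of
any real simulation; conversely, failures on real data (non-stationary
biases before `t_eq`, unconverged replicas) manifest as large block errors
and WHAM non-convergence, both of which are reported, not hidden.

## Known limitations

* Chemical-shift CVs and ensemble shift validation are out of scope; so
  is spectral deconvolution of CD curves.
* The dihedral-box secondary-structure rule is an approximation to
  H-bond-based assignment (see above).
* The WHAM implementation assumes quasi-stationary biases; it does not
  implement time-dependent reweighting.
* `refine_bins()` splits only along binned axes; a bin inconsistent in a
  non-binned CV but already at minimum width stays flagged-but-unsplit.
* Beta-pair templates use idealized strand pairing, not statistics of
  real sheets.
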
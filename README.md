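# idpfel

Free-energy landscapes of intrinsically disordered peptides from
bias-exchange metadynamics data, plus the thermodynamic and
experimental-biophysics analyses that go with them.

## What problem this solves

Intrinsically disordered peptides (the package's motivating case is the
40-residue amyloid-beta fragment) have an *inverted* free-energy
landscape: the global minimum is an expanded, mostly random-coil
ensemble, and partially structured helical or beta-rich conformations lie
only 8–10 kJ/mol higher. One measurable consequence is that such peptides
become **more structured and more compact on heating**, the opposite of
globular-protein unfolding.

`idpfel` is for computational structural biologists who want to

* reconstruct microstate free energies F\_alpha from replicas biased each
  along one collective variable (CV), via the self-consistent
  weighted-histogram (WHAM) equations

  F\_alpha = −kT ln [ Σ\_k n\_k,alpha / Σ\_k N\_k exp((f\_k − V\_k(s\_alpha))/kT) ],
  f\_k = −kT ln Σ\_alpha exp(−(F\_alpha + V\_k(s\_alpha))/kT);

* summarize ensembles by free-energy slices: Boltzmann-weighted secondary
  structure populations, per-residue SASA differences from the global
  minimum, radii of gyration;

* model temperature-induced structuring with a two-state Gibbs–Helmholtz
  stability curve, ΔG(T) = ΔH − TΔS + ΔCp[(T − Tref) − T ln(T/Tref)],
  whose structured-population maximum sits at T\* = Tref − ΔH/ΔCp;

* analyze the bench side: empirical hydrodynamic-radius relations,
  compaction index, Stejskal–Tanner PFG-NMR diffusion fits,
  Stokes–Einstein and internal-standard radii, CD mean-residue
  ellipticity;

* generate every input synthetically with exact ground truth, from
  multi-basin CV landscapes sampled by a bias-exchange Metropolis walker
  to toy peptides with prescribed secondary structure.

## Worked example

Reconstruct a known two-CV landscape from bias-exchange sampling and
check the recovery, then evaluate the thermal two-state model:

```r
library(idpfel)

land <- make_landscape(
  c("cv1", "cv2"),
  wells = list(list(center = c(1.6, 1.5), depth = 25, width = 0.55),
               list(center = c(3.4, 3.2), depth = 17, width = 0.5),
               list(center = c(1.5, 3.4), depth = 14, width = 0.45)),
  domain = list(c(0, 5), c(0, 5)))

sched <- metad_schedule(gaussian_height = 0.30, gaussian_width = 0.2,
                        deposition_stride = 5, exchange_stride = 20,
                        wall_positions = c(4.5, 4.5), t_eq = 40000)
runs <- sample_biased_replicas(land, sched, n_replicas = 2,
                               n_steps = 80000, seed = 1)

spec <- binning_spec(c("cv1", "cv2"), widths = 0.2, t_eq = 40000)
occ  <- assign_microstates(runs, spec)
fes  <- reconstruct_fes(occ, runs, spec, kT = 2.9)
occ
#> microstate_occupancy: 597 microstates over (cv1, cv2), 80000 frames retained, 0 dropped
fes
#> microstate_fes: 597 microstates, kT = 2.9 kJ/mol, F in [0, 74.7], 7 WHAM iterations

truth <- land$F(as.matrix(fes$microstates[, c("center_cv1", "center_cv2")]))
truth <- truth - min(truth)
median(abs(fes$microstates$F - truth)[truth < 40])
#> [1] 0.4741637        # kJ/mol, vs. the 2-3 kJ/mol block-analysis precision

slice_landscape(fes, width = 6)
#> fe_slices: 11 slices of width 6 kJ/mol
#>   [0, 6): 140 microstates
#>   [6, 12): 206 microstates
#>   ...
```

The free energies are exact to ~0.5 kJ/mol (median, below 40 kJ/mol): the
sampler's bias potentials have converged and WHAM combines the two
replicas consistently.

Thermal structuring of a beta-rich state 8 kJ/mol above a disordered
minimum, with ΔH = −60 kJ/mol at 350 K and ΔCp = −1.98 kJ/(mol K) in the
ordering direction:

```r
c2 <- two_state(dG_ref = 8, dH_ref = -60, dCp = -1.98, T_ref = 350,
                name = "beta-rich")
c2
#> two_state [beta-rich]: dG(350 K) = 8, dH = -60 kJ/mol,
#>   dS = -0.1943 kJ/(mol K), dCp = -1.98 kJ/(mol K)
t_max_structured(c2)$T_max
#> [1] 319.697          # K: the structured population peaks near 320 K
```

And the hydrodynamics of a 41-residue construct (4461 Da):

```r
rh_empirical(N = 41, state = "F", basis = "length")   # 13.9 A folded
rh_empirical(N = 41, state = "U", basis = "length")   # 18.4 A unfolded
rh_empirical(M = 4461, state = "PMG")                 # 16.6 A pre-molten globule
compaction_index(15.5, Rh_U = 18.0, Rh_F = 12.4)      # 0.45 at 40 C
```

A measured radius of 15.5 Å at 40 °C gives a compaction index of 0.45 —
between the unfolded (0) and folded (1) endpoints, and higher than at low
temperature: heat-induced compaction.

An end-to-end run over COLVAR-style tables and bias-grid files, writing
TSV outputs and a JSON manifest, is available as `run_pipeline()`; see
`?run_pipeline` and the methods vignette (`vignettes/idpfel-methods.Rmd`)
for the model's assumptions and numerical choices.

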
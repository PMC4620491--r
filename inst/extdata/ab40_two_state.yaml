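# Two-state Gibbs-Helmholtz inputs for the 40-residue amyloid-beta
# peptide: a beta-rich state (C2) 8 kJ/mol and a helix-rich state (C3)
# 10 kJ/mol above the disordered global minimum (C1) at 350 K, with
# enthalpy differences of -60 and -28 kJ/mol estimated from restrained
# simulations and a heat-capacity difference of magnitude 1.98 kJ/(mol K)
# taken negative in the ordering (U -> S) direction.
#
# The radii of gyration are illustrative values for the mixture-Rg curve:
# 13 A for the disordered minimum ensemble; compact structured states are
# SYNTHETIC placeholders, not measured values.
rg_unstructured: 13.0
states:
  - name: C2
    dG_ref: 8
    dH_ref: -60
    dCp: -1.98
    T_ref: 350
    rg: 9.5
  - name: C3
    dG_ref: 10
    dH_ref: -28
    dCp: -1.98
    T_ref: 350
    rg: 10.5
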
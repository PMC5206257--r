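# Coarse-grained cyclohexane: three bonded, uncharged Lennard-Jones
# beads per molecule.  sigma = 4.1 Angstrom and epsilon = 3.19 kJ/mol are
# the lipid-tail bead values scaled by the 0.9 ring-bead factor (stored
# directly).  Bond convention: E = k (r - r0)^2.
sites:
  CHX:
    kind: cg_cyclohexane
    sigma: 4.1         # Angstrom
    epsilon: 3.19      # kJ/mol
    mass: 28.053       # g/mol (one third of C6H12)
bonds:
  - {i: 1, j: 2, r0: 4.05, k: 12.69}
  - {i: 2, j: 3, r0: 4.05, k: 12.69}
  - {i: 3, j: 1, r0: 4.05, k: 12.69}
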
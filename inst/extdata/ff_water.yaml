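# Coarse-grained Stockmayer water: one point-dipole Lennard-Jones bead
# per molecule.  sigma/epsilon/dipole follow the published Elba water
# model (not restated in the accompanying study); rot_inertia is a
# water-like configuration choice.  dipole is in e*Angstrom (2.6 D).
sites:
  W:
    kind: cg_water
    sigma: 3.05        # Angstrom
    epsilon: 2.30      # kJ/mol
    dipole: 0.54131    # e*Angstrom
    mass: 18.015       # g/mol
    rot_inertia: 2.0   # g/mol*Angstrom^2
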
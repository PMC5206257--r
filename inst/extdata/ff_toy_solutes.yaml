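# Toy solutes standing in for challenge compounds: a neutral LJ site, a
# charged LJ site (exercises the charge-dipole path in water) and a
# constrained diatomic (exercises SHAKE).
sites:
  LJS:
    kind: atom
    sigma: 3.5
    epsilon: 0.5
    mass: 16.0
  QS:
    kind: atom
    sigma: 3.5
    epsilon: 0.5
    charge: 0.5
    mass: 16.0
  DA:
    kind: atom
    sigma: 3.5
    epsilon: 0.5
    mass: 16.0
  DB:
    kind: atom
    sigma: 2.5
    epsilon: 0.1
    mass: 1.008
constraints:
  - {i: 1, j: 2, d: 1.09}   # for the DA-DB diatomic
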
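# Reference electronic state for 3-hexanone (AM1-derived values).
# Atom indices follow the parsed SMILES CCC(=O)CCC: C1 C2 C3 O4 C5 C6 C7.
# The raw set_value entries for the carbonyl pair (atoms 3 and 4) are
# back-calculated from their published dipole-scaled effective values
# (0.3899 and 1.9507) by dividing out the dipolar factor 1.7193.
name: 3-hexanone
dipole_debye: 2.6790
polar_group:
  carbon: 3
  heteroatom: 4
  bond_length_angstrom: 1.2342
atoms:
  - {index: 1, element: C, set_value: 0.9892}
  - {index: 2, element: C, set_value: 0.9998}
  - {index: 3, element: C, net_charge_e: 0.224, set_value: 0.22677834}
  - {index: 4, element: O, net_charge_e: -0.288, set_value: 1.13458966}
  - {index: 5, element: C, set_value: 0.9998}
  - {index: 6, element: C, set_value: 0.8988}
  - {index: 7, element: C, set_value: 0.9998}
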
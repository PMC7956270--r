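# Mapping from GRO residue/atom names to liqstruct atom roles.
# Keys are residue names; values map atom-name prefixes to roles.
# Atom names are matched first by exact name, then by leading element letter(s).
water:
  residues: [SOL, HOH, WAT, TIP4, SPC]
  atoms:
    OW: water_O
    HW1: water_H
    HW2: water_H
    O: water_O
    H1: water_H
    H2: water_H
methanol:
  residues: [MET, MOH, MTL, MeOH]
  atoms:
    O: hydroxyl_O
    OH: hydroxyl_O
    HO: hydroxyl_H
    OW: hydroxyl_O
    C: methyl_C
    CT: methyl_C
    H1: methyl_H
    H2: methyl_H
    H3: methyl_H
    HC1: methyl_H
    HC2: methyl_H
    HC3: methyl_H
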
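# Default tubulin domain map: (subunit, inclusive residue-number ranges)
# -> domain label, following the standard tubulin secondary-structure
# nomenclature (T1-T7 loops, H1-H12 helices, S1-S10 strands, M-loop).
# Ranges are approximate conventions and are meant to be edited to match
# the numbering of the template model in use; the map is data, not code.
# Residues not covered aggregate under "unassigned". Cofactor residues
# are mapped by residue name in the `resnames` block.
alpha:
  N-terminal loop: [[1, 9]]
  T2 loop: [[63, 72]]
  H2-S3 loop: [[81, 90]]
  T3 loop: [[98, 106]]
  H3 helix: [[107, 128]]
  T5 loop: [[171, 180]]
  T7 loop: [[244, 251]]
  H8 helix: [[252, 260]]
  H8-S7 loop: [[261, 268]]
  M-loop: [[272, 288]]
  H9 helix: [[289, 306]]
  H10 helix: [[325, 337]]
  H10-S9 loop: [[338, 348]]
  S9 strand: [[349, 356]]
  H11 helix: [[383, 395]]
  H11-H11' loop: [[396, 402]]
  H11' helix: [[403, 410]]
  H12 helix: [[418, 432]]
  C-terminal tail: [[433, 451]]
beta:
  N-terminal loop: [[1, 9]]
  H1'-S2 loop: [[38, 48]]
  T2 loop: [[63, 72]]
  H2-S3 loop: [[81, 90]]
  H2'' helix: [[91, 97]]
  T3 loop: [[98, 106]]
  H3 helix: [[107, 128]]
  H3-S4 loop: [[129, 136]]
  T5 loop: [[171, 180]]
  T7 loop: [[244, 251]]
  H8 helix: [[252, 260]]
  H8-S7 loop: [[261, 268]]
  M-loop: [[272, 288]]
  H9 helix: [[289, 306]]
  H10 helix: [[325, 337]]
  H10-S9 loop: [[338, 348]]
  S9 strand: [[349, 356]]
  H11 helix: [[383, 395]]
  H11-H11' loop: [[396, 402]]
  H11' helix: [[403, 410]]
  H12 helix: [[418, 428]]
  C-terminal tail: [[429, 445]]
resnames:
  GTP: cofactor
  GDP: cofactor
  MG: Mg2+
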
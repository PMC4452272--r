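# Domain map for the synthetic bead dimer (make_toy_dimer): the first two
# residues of each subunit stand in for the lateral-contact M-loop, the
# next two for the H3 helix; cofactor beads map by residue name.
alpha:
  M-loop: [[1, 2]]
  H3 helix: [[3, 4]]
beta:
  M-loop: [[1, 2]]
  H3 helix: [[3, 4]]
resnames:
  GTP: cofactor
  GDP: cofactor
  MG: Mg2+
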
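# Example per-ring component groupings (kcal/mol): the van der Waals plus
# non-polar solvation sum E(vdW+SA) and the electrostatic plus polar
# solvation sum E(ele+GB) for each model and interface class. Their sum
# reproduces the corresponding per-ring total.
model	class	E_vdW_SA	E_ele_GB
GDP	lateral	-1476	1065
GTP	lateral	-1432	950
GDP	longitudinal	-2668	1428
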
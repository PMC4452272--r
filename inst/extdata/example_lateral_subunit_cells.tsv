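# Example ligand/receptor-by-subunit contributions to lateral stability,
# kcal/mol per microtubule ring, for a GDP-state and a GTP-state model
# (published reference values; sd columns are the reported spreads).
model	subunit	role	energy	sd
GDP	beta	L	-25	14
GDP	beta	R	-147	15
GDP	alpha	L	-165	14
GDP	alpha	R	-74	15
GTP	beta	L	-61	14
GTP	beta	R	-145	16
GTP	alpha	L	-193	15
GTP	alpha	R	-83	14
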
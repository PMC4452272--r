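# Example ligand/receptor-by-subunit contributions to longitudinal
# stability, kcal/mol per microtubule ring, for a GDP-state and a
# GTP-state model (published reference values; the cross terms L.alpha
# and R.beta are essentially zero at this interface).
model	subunit	role	energy	sd
GDP	beta	L	-664	24
GDP	beta	R	0	0
GDP	alpha	L	0	0
GDP	alpha	R	-576	21
GTP	beta	L	-623	22
GTP	beta	R	0	0
GTP	alpha	L	0	0
GTP	alpha	R	-475	20
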
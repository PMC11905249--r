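table	rows	version
H	34	1
C	34	1
Al	36	1
O	34	1
N	34	1
Ca	36	1
Ti	36	1
I	36	1
F	34	1
Na	34	1
Mg	34	1
P	34	1
S	34	1
Cl	34	1
Ar	34	1
K	34	1
water	34	1
air	34	1
pmma	34	1
teflon	34	1
soft_tissue	34	1
lung	34	1
cortical_bone	36	1
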
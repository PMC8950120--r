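# van der Waals radii (Angstrom) used for SASA and the PB dielectric cavity.
# Element-keyed defaults (Bondi-like, protein heavy atoms); hydrogens carry
# radius 0 -- their surface is subsumed by the bonded heavy atom. Edit freely.
element	radius
H	0.0
C	1.70
N	1.55
O	1.52
S	1.80
P	1.80
SE	1.90
FE	1.40
ZN	1.39
MG	1.18
NA	1.36
CL	1.81
K	1.76
CA	1.37
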
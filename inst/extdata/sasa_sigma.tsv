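# Nonpolar solvation coefficients sigma (kcal/(mol Angstrom^2)) per element:
# positive for hydrophobic (carbon, sulfur), negative for hydrophilic
# (nitrogen, oxygen) groups. Editable defaults in the spirit of
# atomic-solvation-parameter sets.
element	sigma
H	0.0
C	0.012
S	0.012
N	-0.060
O	-0.060
P	-0.060
SE	0.012
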
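# Default partial charges (elementary charges) for the PB polar term:
# formal side-chain charges at pH 7 split over the equivalent atoms of each
# ionizable group. All unlisted atoms carry 0. Editable; force-field charge
# sets can be substituted via assign_parameters(charge_table = ...).
resname	name	charge
ASP	OD1	-0.5
ASP	OD2	-0.5
GLU	OE1	-0.5
GLU	OE2	-0.5
LYS	NZ	1.0
ARG	NH1	0.5
ARG	NH2	0.5
HIS	ND1	0.0
HIS	NE2	0.0
ION	NA	1.0
ION	CL	-1.0
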
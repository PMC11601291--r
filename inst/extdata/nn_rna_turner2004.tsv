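term	key	dg37_kcal_mol
# Nearest-neighbor free-energy parameters for RNA/RNA duplexes at 37 C,
# Watson-Crick block of the Turner-2004 vintage (Xia et al. 1998 values).
# Stack keys are written top strand 5'->3' "/" bottom strand 3'->5', so the
# first characters of each side pair with each other. G:U wobble stack
# parameters are deliberately not shipped: duplexes with declared wobbles
# require a user-supplied table carrying the wobble block.
stack	AA/UU	-0.93
stack	UU/AA	-0.93
stack	AU/UA	-1.10
stack	UA/AU	-1.33
stack	CU/GA	-2.08
stack	AG/UC	-2.08
stack	CA/GU	-2.11
stack	UG/AC	-2.11
stack	GU/CA	-2.24
stack	AC/UG	-2.24
stack	GA/CU	-2.35
stack	UC/AG	-2.35
stack	CG/GC	-2.36
stack	GG/CC	-3.26
stack	CC/GG	-3.26
stack	GC/CG	-3.42
init	duplex	4.09
term_au	per_end	0.45
symmetry	self	0.43
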
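name	smarts
nitro_group	[N+](=O)[O-]
nitro_group	N(=O)=O
aldehyde	[CX3H1](=O)[#6]
acyl_halide	[CX3](=O)[F,Cl,Br,I]
alkyl_halide	[CX4][Cl,Br,I]
michael_acceptor_enone	C=CC=O
michael_acceptor_nitrile	C=CC#N
peroxide	[#8]-[#8]
disulfide	[#16]-[#16]
thiol	[SX2H]
hydrazine	[NX3]-[NX3]
azo	[#6]N=N[#6]
nitroso	[#6][NX2]=O
oxime	C=NO
acyclic_imine	[CX3]=[NX2][#6]
isocyanate	N=C=O
isothiocyanate	N=C=S
epoxide	C1OC1
aziridine	C1NC1
quaternary_nitrogen	[N+X4]
phosphorus	[#15]
sulfonyl_halide	S(=O)(=O)[F,Cl,Br,I]
sulfonate_ester	[#6]OS(=O)(=O)[#6]
anhydride	C(=O)OC(=O)
thiourea	NC(=S)N
thioamide	[#6]C(=S)N
phenol_ester	cOC(=O)[#6]
aliphatic_long_chain	[CH2][CH2][CH2][CH2][CH2][CH2][CH2]
polyene	C=CC=CC=C
diketone	C(=O)C(=O)
hetero_halide	[N,O,S][Cl,Br,I]
carbodiimide	N=C=N
triflate	OS(=O)(=O)C(F)(F)F
crown_ether_motif	OCCOCCOCCO
hydroxamic_acid	C(=O)N[OH]
azide	N=[N+]=[N-]
diazonium	[N+]#N
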
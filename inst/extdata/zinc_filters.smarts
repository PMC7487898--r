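# Functional-group exclusion catalog used by the construction environment's
# filter reward. One rule per line: <name><TAB><SMARTS>. Lines starting with
# '#' are comments. This is an editable, documented stand-in for the reactive
# and undesirable-group filters applied to commercial screening libraries.
acyl_halide	[CX3](=[OX1])[F,Cl,Br,I]
sulfonyl_halide	[SX4](=[OX1])(=[OX1])[F,Cl,Br,I]
peroxide	[OX2][OX2]
azide	[NX1]~[NX2]~[NX2,NX1]
diazo	[CX2]=[NX2+]=[NX1-]
isocyanate	[NX2]=[CX2]=[OX1]
isothiocyanate	[NX2]=[CX2]=[SX1]
nitroso	[NX2]=[OX1]
n_nitroso	[NX3][NX2]=[OX1]
aldehyde_reactive	[CX3H1](=O)[#6][F,Cl,Br,I]
alpha_halo_ketone	[CX3](=[OX1])[CX4][F,Cl,Br,I]
anhydride	[CX3](=[OX1])[OX2][CX3](=[OX1])
thiocyanate	[SX2][CX2]#[NX1]
phosphorus_halide	[PX3,PX4][F,Cl,Br,I]
silicon	[Si]
michael_acceptor_nitrile	[CX3]=[CX3][CX2]#[NX1]
hydrazine	[NX3][NX3]
three_membered_heterocycle	[O,N,S]1[CX4][CX4]1
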
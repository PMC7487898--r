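# Structural-alert catalog consulted by the drug-likeness (QED) ALERTS
# descriptor. One rule per line: <name><TAB><SMARTS>; '#' comments.
nitro	[NX3+](=O)[O-]
nitro_neutral	[NX3](=O)=O
azo	[NX2]=[NX2]
thiol	[SX2H]
michael_acceptor	[CX3]=[CX3][CX3]=[OX1]
quaternary_n	[NX4+]
acyl_halide	[CX3](=[OX1])[F,Cl,Br,I]
peroxide	[OX2][OX2]
hydrazine	[NX3][NX3]
imine	[CX3]=[NX2][!#8]
polyene	[CX3]=[CX3][CX3]=[CX3][CX3]=[CX3]
long_chain	[CX4H2][CX4H2][CX4H2][CX4H2][CX4H2][CX4H2][CX4H2]
phenol_ortho_nitro	[OX2H]c1ccccc1[NX3+](=O)[O-]
crown_like	[OX2][CX4][CX4][OX2][CX4][CX4][OX2]
iodine_excess	[#53]
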
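name	smarts
nitro	[N+](=O)[O-]
aromatic_nitro	c[N+](=O)[O-]
primary_aromatic_amine	c[NH2]
azo	N=N
nitroso	[NX2]=O
epoxide	C1OC1
aziridine	C1NC1
aliphatic_halide	[CX4][Cl,Br,I]
michael_acceptor	C=CC=O
hydrazine	[NX3][NX3]
aldehyde	[CX3H1]=O
isocyanate	N=C=O
polycyclic_aromatic	c1ccc2ccccc2c1
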
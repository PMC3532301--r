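id	smiles	name
C00001	O	H2O
C00011	O=C=O	CO2
C00014	N	NH3
C01010	NC(=O)NC(O)=O	Urea-1-carboxylate
C00025	N[C@@H](CCC(O)=O)C(O)=O	L-Glutamate
C00217	N[C@H](CCC(O)=O)C(O)=O	D-Glutamate
C00019	C[S+](CC[C@H](N)C(O)=O)C[C@H]1O[C@@H](n2cnc3c(N)ncnc32)[C@H](O)[C@@H]1O	S-Adenosyl-L-methionine
C00021	OC(=O)[C@@H](N)CCSC[C@H]1O[C@@H](n2cnc3c(N)ncnc32)[C@H](O)[C@@H]1O	S-Adenosyl-L-homocysteine
C00078	N[C@@H](Cc1c[nH]c2ccccc12)C(O)=O	L-Tryptophan
C00643	CN[C@@H](Cc1c[nH]c2ccccc12)C(O)=O	Abrine
C00780	NCCc1c[nH]c2ccc(O)cc12	Serotonin
C02718	CNCCc1c[nH]c2ccc(O)cc12	N-Methylserotonin
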
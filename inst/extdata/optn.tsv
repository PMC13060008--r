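#namespace=optn version=2025-01-15
atom	class	locus	chain_role	partner_loci
A2	ANTIGEN	A		
A24	ANTIGEN	A		
A68	ANTIGEN	A		
A69	ANTIGEN	A		
B7	ANTIGEN	B		
B57	ANTIGEN	B		
B58	ANTIGEN	B		
DR2	ANTIGEN	DRB1		
52	ANTIGEN	DRB3		
DQ2	ANTIGEN	DQ	BETA	DQA
84DEAV	EPITOPE	DPB1		
Bw4	EPITOPE	B		
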
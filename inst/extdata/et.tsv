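#namespace=et version=2025-03-01
atom	class	locus	chain_role	partner_loci
A2	ANTIGEN	A		
B7	ANTIGEN	B		
DQ2	ANTIGEN	DQ	BETA	DQA
SDQA05	MATCH_DETERMINANT	DQA	ALPHA	DQ
DQA05	MATCH_DETERMINANT	DQA	ALPHA	DQ
DPA01	ANTIGEN	DPA	ALPHA	DPB
DPB0402	ANTIGEN	DPB	BETA	DPA
DP-0402	ASSOCIATED_ANTIGEN	DPB1		
DP105	ANTIGEN	DPB1		
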
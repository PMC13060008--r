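#namespace=who version=3.58.0
atom	class	locus	chain_role	partner_loci
A*01:01	PROTEIN	A		
A*01:02	PROTEIN	A		
A*02:01	PROTEIN	A		
A*02:02	PROTEIN	A		
A*24:03	PROTEIN	A		
A*24:09N	PROTEIN	A		
B*07:02	PROTEIN	B		
B*08:01	PROTEIN	B		
DRB1*08:07	PROTEIN	DRB1	BETA	DRA
DRB1*03:01	PROTEIN	DRB1	BETA	DRA
DRA*01:01	PROTEIN	DRA	ALPHA	DRB1|DRB3|DRB4|DRB5
DQA1*05:01	PROTEIN	DQA1	ALPHA	DQB1
DQB1*02:01	PROTEIN	DQB1	BETA	DQA1
DQB1*03:01	PROTEIN	DQB1	BETA	DQA1
DPA1*01:03	PROTEIN	DPA1	ALPHA	DPB1
DPA1*01:04	PROTEIN	DPA1	ALPHA	DPB1
DPA1*02:01	PROTEIN	DPA1	ALPHA	DPB1
DPB1*02:01	PROTEIN	DPB1	BETA	DPA1
DPB1*02:02	PROTEIN	DPB1	BETA	DPA1
DPB1*04:01	PROTEIN	DPB1	BETA	DPA1
DPB1*04:02	PROTEIN	DPB1	BETA	DPA1
DPB1*06:01	PROTEIN	DPB1	BETA	DPA1
DPB1*105:01	PROTEIN	DPB1	BETA	DPA1
A9	ANTIGEN	A		
A24	ANTIGEN	A		
B7	ANTIGEN	B		
DR2	ANTIGEN	DRB1		
Cw9	ANTIGEN	C		
DPw2	ANTIGEN	DPB1		
Bw4	EPITOPE	B		
Bw6	EPITOPE	B		
A2402	ASSOCIATED_ANTIGEN	A		
A2403	ASSOCIATED_ANTIGEN	A		
B5102	ASSOCIATED_ANTIGEN	B		
A-0265	ASSOCIATED_ANTIGEN	A		
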
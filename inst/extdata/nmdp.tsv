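#namespace=nmdp version=2025-02-01
atom	class	locus	chain_role	partner_loci
A*01:01	PROTEIN	A		
A*02:01	PROTEIN	A		
A*02:02	PROTEIN	A		
A*02:03	PROTEIN	A		
B*07:02	PROTEIN	B		
A*02:AB	MAC	A		
A*02:AC	MAC	A		
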
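record_id	chain_id	cath_code	segments
R1	A	3.40.50.720	1-30
R2	A	3.40.50.970	1-20
R2	B	3.40.50.970	1-15
R2	B	1.10.600.10	16-30
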
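record_id	biological_unit_chains	catalytic_unit_chains	ec_nodes	has_structure
R1	A	A	1.1.1.1	TRUE
R2	A,B	A,B	2.7.11.1;3.4.-.-	FALSE
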
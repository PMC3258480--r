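record_id	chain_id	position	residue_type	function_context	involvement	roles	acting_part
R1	A	5	H	catalytic	reactant	proton_shuttle;stabilization	side_chain
R2	A	4	D	catalytic	spectator	activation	side_chain
R2	B	6	K	catalytic	reactant	covalent_catalysis	side_chain
R2	B	11	W	binding			main_chain_NH
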
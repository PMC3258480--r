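record_id	cofactor_id	entity_kind	roles
R1	ZN	metal_ion	electron_shuttle;stabilization
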
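pdb_id	group	protein_selector	dna_chains	scope
synthetic_ngomiv_like	HS	A	E,H	chain
synthetic_sigmae4_like	HS	A	B,C	chain
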
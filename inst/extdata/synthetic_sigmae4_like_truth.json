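{"n_pairs":8,"n_scb_strand1":2,"n_scb_strand2":2,"bonds":{"strand":[1,1,2,2],"dna_chain":["B","B","C","C"],"dna_resno":[2,4,3,1],"dna_atom":["N7","N7","O4","O4"],"groove":["major","major","major","major"],"prot_resno":[1,2,3,4],"prot_resid":["ASN","ASN","ASN","ASN"]},"engaged":{"strand":[1,1,2,2],"dna_chain":["B","B","C","C"],"dna_resno":[2,4,3,1],"groove":["major","major","major","major"]},"n_bases_s1":2,"n_bases_s2":2,"n_bases_major_s1":2,"n_bases_major_s2":2,"is_5050_bonds":true,"is_5050_bases_major":true,"one_strand_only":false,"pct_dominant":50,"dominant_strand":"strand1","bp_engaged_steps":[],"bp_engaged_types":[],"bp_engaged_steps_major":[]}
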
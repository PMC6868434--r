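{"n_pairs":8,"n_scb_strand1":3,"n_scb_strand2":3,"bonds":{"strand":[1,1,1,2,2,2],"dna_chain":["E","E","E","H","H","H"],"dna_resno":[7,8,9,6,5,4],"dna_atom":["O6","N7","O2","O2","O4","O6"],"groove":["major","major","minor","minor","major","major"],"prot_resno":[1,2,3,4,5,6],"prot_resid":["ASN","ASN","ASN","ASN","ASN","ASN"]},"engaged":{"strand":[1,1,1,2,2,2],"dna_chain":["E","E","E","H","H","H"],"dna_resno":[7,8,9,6,5,4],"groove":["major","major","minor","minor","major","major"]},"n_bases_s1":3,"n_bases_s2":3,"n_bases_major_s1":2,"n_bases_major_s2":2,"is_5050_bonds":true,"is_5050_bases_major":true,"one_strand_only":false,"pct_dominant":50,"dominant_strand":"strand1","bp_engaged_steps":[3,4,5],"bp_engaged_types":["GC","AT","GC"],"bp_engaged_steps_major":4}
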
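lineage	k_taxa	n_resolved	n_separating	n_matching
I	4	39	31	8
II	3	90	55	38
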
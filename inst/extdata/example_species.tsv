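species_id	phylum	has_kdpE	has_dac	chain_accessions
species_00001	Archaea	0	1	SYN00001_1
species_00002	Bacteroidota	1	0	SYN00002_1
species_00003	Pseudomonadota	1	1	SYN00003_1
species_00004	Pseudomonadota	1	1	SYN00004_1
species_00005	Campylobacterota	1	0	SYN00005_1
species_00006	Chloroflexota	1	1	SYN00006_1
species_00007	Acidobacteriota	1	0	SYN00007_1
species_00008	Archaea	1	1	SYN00008_1
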
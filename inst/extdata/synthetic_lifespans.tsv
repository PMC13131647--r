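species_id	max_lifespan_years
Homo_sapiens	122.5
Pan_troglodytes	59.4
Balaena_mysticetus	211
Tursiops_truncatus	51.6
Cavia_porcellus	12
Heterocephalus_glaber	31
Mus_musculus	4
Bos_taurus	20
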
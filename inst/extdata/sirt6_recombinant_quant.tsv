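peptide	protein_id	site_label	is_modified	localization_prob	intensity	protein_prob	fixed_mods
ALSPGYK	SIRT6	S10	TRUE	0.97	42800000	0.99	
ALSPGYK	SIRT6		FALSE	NA	1.42e+09	0.99	
VLETPAWDGK	SIRT6	T294	TRUE	0.99	1.6e+10	0.99	
VLETPAWDGK	SIRT6		FALSE	NA	1.81e+10	0.99	
LNSPELK	SIRT6	S303	TRUE	0.96	6.47e+08	0.99	
LNSPELK	SIRT6		FALSE	NA	55500000	0.99	
EQSPAGHSPVR	SIRT6	S326	TRUE	0.95	0	0.99	
EQSPAGHSPVR	SIRT6	S330	TRUE	0.98	1.73e+09	0.99	
EQSPAGHSPVR	SIRT6		FALSE	NA	1.13e+09	0.99	
AVTSPGLK	SIRT6	T337	TRUE	0.92	8.47e+09	0.99	
AVTSPGLK	SIRT6	S338	TRUE	0.99	8.59e+09	0.99	
AVTSPGLK	SIRT6		FALSE	NA	1.03e+08	0.99	
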
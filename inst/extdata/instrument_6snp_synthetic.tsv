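snp_id	effect_allele	weight	allele_freq
rs3755967	C	0.089	0.72
rs12785878	T	0.036	0.75
rs10741657	A	0.031	0.40
rs17216707	T	0.026	0.79
rs10745742	T	0.017	0.40
rs8018720	G	0.017	0.18
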
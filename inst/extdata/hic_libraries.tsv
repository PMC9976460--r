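short_name	genome_size	n_paired_reads	read_length	library_depth	accession
ANABR	884566040	174148156	150	59.0622344	SRX5337861
BRAFL	513461369	115383056	147	66.06654466	SRX3274438
DROME	143726002	88682876	100	123.4054726	SRX2947125
CAEEL	100286401	666058021	101	1341.594861	SRX2638356
RHOES	256689583	203573974	150	237.9223632	SRX8210228
ACHFU	1855892613	696378573	150	112.5677049	SRX5181756
HUDVU	847270819	712495485	100	168.1860083	SRX14496554
PECMA	918306378	241297364	151	79.35456583	SRX6848914
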
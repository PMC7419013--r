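stage	class	n_fc_in	n_fc_total	n_bg_in	n_bg_total	log2_enrichment
zygote	MIR	0	10	260	10000	     -Inf
zygote	Alu	0	10	985	10000	     -Inf
zygote	exon	0	10	446	10000	     -Inf
zygote	tts	0	10	214	10000	     -Inf
zygote	ALR	0	10	335	10000	     -Inf
zygote	ERVL-MaLR	0	10	324	10000	     -Inf
zygote	intron	1	10	2213	10000	-1.1460035
zygote	promoter	0	10	197	10000	     -Inf
zygote	L1	5	10	1520	10000	1.7178568
zygote	SVA	0	10	7	10000	     -Inf
zygote	cgi	0	10	116	10000	     -Inf
zygote	L2	1	10	298	10000	1.7466158
zygote	ERV1	1	10	196	10000	2.3510744
zygote	ERVL	0	10	192	10000	     -Inf
zygote	ERVK	0	10	78	10000	     -Inf
two_cell	MIR	0	10	260	10000	     -Inf
two_cell	Alu	0	10	985	10000	     -Inf
two_cell	exon	0	10	446	10000	     -Inf
two_cell	tts	0	10	214	10000	     -Inf
two_cell	ALR	0	10	335	10000	     -Inf
two_cell	ERVL-MaLR	0	10	324	10000	     -Inf
two_cell	intron	1	10	2213	10000	-1.1460035
two_cell	promoter	0	10	197	10000	     -Inf
two_cell	L1	5	10	1520	10000	1.7178568
two_cell	SVA	0	10	7	10000	     -Inf
two_cell	cgi	0	10	116	10000	     -Inf
two_cell	L2	1	10	298	10000	1.7466158
two_cell	ERV1	1	10	196	10000	2.3510744
two_cell	ERVL	0	10	192	10000	     -Inf
two_cell	ERVK	0	10	78	10000	     -Inf
four_cell	MIR	0	8	260	10000	     -Inf
four_cell	Alu	0	8	985	10000	     -Inf
four_cell	exon	0	8	446	10000	     -Inf
four_cell	tts	0	8	214	10000	     -Inf
four_cell	ALR	0	8	335	10000	     -Inf
four_cell	ERVL-MaLR	0	8	324	10000	     -Inf
four_cell	intron	1	8	2213	10000	-0.82407536
four_cell	promoter	0	8	197	10000	     -Inf
four_cell	L1	4	8	1520	10000	1.7178568
four_cell	SVA	0	8	7	10000	     -Inf
four_cell	cgi	0	8	116	10000	     -Inf
four_cell	L2	1	8	298	10000	2.0685439
four_cell	ERV1	1	8	196	10000	2.6730025
four_cell	ERVL	0	8	192	10000	     -Inf
four_cell	ERVK	0	8	78	10000	     -Inf
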
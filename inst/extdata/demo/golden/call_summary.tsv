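cell_id	stage	sequenced_cpg	n_candidate	n_fc	n_unmod	abundance
treated_1	zygote	9951	6	6	8654	0.00060295448
treated_2	zygote	9932	8	8	8691	0.00080547725
treated_3	zygote	9937	7	7	8662	0.00070443796
treated_4	zygote	9934	6	6	8699	0.00060398631
treated_5	two_cell	9925	7	7	8674	0.00070528967
treated_6	two_cell	9933	9	9	8684	0.00090607067
treated_7	two_cell	9926	5	5	8637	0.00050372758
treated_8	two_cell	9932	7	7	8631	0.00070479259
treated_9	four_cell	9932	6	6	8678	0.00060410793
treated_10	four_cell	9919	5	5	8666	0.00050408307
untreated_1	control	9926	0	0	8706	        0
untreated_2	control	9943	0	0	8662	        0
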
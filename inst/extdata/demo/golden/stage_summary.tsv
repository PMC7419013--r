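stage	n_cells	merged_fc	common_covered	stage_fc_fraction	fc_level
zygote	4	10	5819	0.00068740333	    0.001
two_cell	4	10	5789	0.0010364484	0.0010002
four_cell	2	8	7616	0.00052521008	0.00081333876
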
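cell_id	treatment	conversion_rate	background_rate	background_source	flagged	stage
treated_1	treated	0.84108527	0.011226945	cell	FALSE	zygote
treated_10	treated	0.80603448	0.0099497487	cell	FALSE	four_cell
treated_2	treated	0.79352227	0.012224449	cell	FALSE	zygote
treated_3	treated	0.77959184	0.011229196	cell	FALSE	zygote
treated_4	treated	0.78597786	0.012281055	cell	FALSE	zygote
treated_5	treated	0.78571429	0.010528427	cell	FALSE	two_cell
treated_6	treated	0.82641509	0.011220336	cell	FALSE	two_cell
treated_7	treated	0.81632653	0.01372608	cell	FALSE	two_cell
treated_8	treated	0.81376518	0.011545735	cell	FALSE	two_cell
treated_9	treated	0.78297872	0.0091616589	cell	FALSE	four_cell
untreated_1	untreated	0.019305019	0.0110661	cell	FALSE	control
untreated_2	untreated	0.0076923077	0.011548504	cell	FALSE	control
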
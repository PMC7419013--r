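from	to	inherited	newly_generated	undetermined
zygote	two_cell	10	0	0
two_cell	four_cell	8	0	0
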
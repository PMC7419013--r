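chr1	235000	236000
chr1	312000	313000
chr1	363000	364000
chr1	395000	396000
chr1	446000	447000
chr1	467000	468000
chr1	473000	474000
chr1	545000	546000
chr1	579000	580000
chr1	881000	882000
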
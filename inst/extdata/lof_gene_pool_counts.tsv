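group	n_lof
native	1168
hybrid	1220
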
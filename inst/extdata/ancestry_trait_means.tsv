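table	group	trait	mean	n
litters	native_x_native	litter_size	6.30	37
litters	native_x_immigrant	litter_size	11.17	6
litters	native_x_immigrantF14	litter_size	5.14	59
litters	immigrantF14_x_immigrantF14	litter_size	6.05	19
individuals	native	life_span	3.8	30
individuals	F1	life_span	4.8	21
individuals	F2F3	life_span	3.2	34
individuals	native	lrs	7.60	30
individuals	F1	lrs	12.19	21
individuals	F2F3	lrs	6.94	34
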
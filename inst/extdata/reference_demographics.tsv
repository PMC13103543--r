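variable	group	n	mean	sd	count_m	count_f
age	control	445	36.11	14.82
age	patient	442	36.47	12.77
sex	control	445			165	280
sex	patient	442			163	279
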
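state	n	mean	sd
1	836	0.198	0.043
2	886	0.106	0.025
3	826	0.288	0.056
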
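transition	mean_hc	sd_hc	n_hc	mean_mdd	sd_mdd	n_mdd
1to2	4.98	3.67	445	4.73	3.56	442
1to3	2.64	2.70	445	2.37	2.73	442
2to1	4.99	3.64	445	4.69	3.59	442
2to3	4.81	3.69	445	4.27	3.48	442
3to1	2.64	2.71	445	2.45	2.79	442
3to2	4.78	3.70	445	4.12	3.45	442
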
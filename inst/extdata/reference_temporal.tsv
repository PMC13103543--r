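metric	mean_hc	sd_hc	n_hc	mean_mdd	sd_mdd	n_mdd
transitions	24.84	8.45	445	22.63	9.33	442
occupancy_state1	0.23	0.19	445	0.22	0.17	442
occupancy_state2	0.513	0.219	445	0.553	0.240	442
occupancy_state3	0.25	0.18	445	0.23	0.19	442
dwell_state1	5.71	3.45	445	5.74	3.54	442
dwell_state2	13.43	18.15	445	18.44	27.11	442
dwell_state3	6.75	4.76	445	6.29	4.28	442
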
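gene	n_cpgs	width_bp	status
HSD17B2	8	1167	Hypomethylated
HSD17B2	3	40	Hypomethylated
HSD17B8	5	215	Hypermethylated
HSD17B10	7	250	Hypermethylated
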
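category	n_sequences	total_length	gc_pct	avg_length_printed	max_length
genes	941	20074601	44.54	10531	32759
cds	2419	2568639	55.81	1061	15018
introns	2403	64787126	43.65	7435	32753
utr5	2048	491916	59.87	240	3474
utr3	1758	1287596	48.10	732	11007
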
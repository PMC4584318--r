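category	n_repeats	n_alus	pct_seq_with_repeats	pct_seq_with_alus	nt_per_alu_printed	pct_covered_by_alus
genes	37101	11335	81.08	59.29	1771	15.03
cds	660	56	20.95	1.77	45868	0.17
introns	125952	40990	92.09	80.44	1580	16.53
utr5	582	68	20.41	3	7234	1.83
utr3	1025	217	30.48	8.02	5933	3.88
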
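region	gene_set	n_sense	n_antisense
utr5	t1d	17	51
utr3	t1d	112	105
utr5	background	681	2028
utr3	background	6075	5867
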
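spec_id	target_id	context	type	state	sites	windows	min_run
first2_cg_open	TGT001	CG	set	unmethylated	0,1	.	.
cg_run6_meth	TGT002	CG	run	methylated	.	.	6
cg_run2_meth_5prime	TGT003	CG	run	methylated	.	0-1	2
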
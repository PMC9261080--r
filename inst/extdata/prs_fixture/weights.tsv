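snp_id	effect_allele	OR	p
rs1	A	1.5	1e-8
rs2	C	0.8	1e-5
rs3	A	2.0	1e-4
rs4	T	1.2	0.5
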
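snp_id	chrom	pos	effect_allele	other_allele
rs1	1	1000	A	G
rs2	1	600000	C	T
rs3	2	5000	G	A
rs4	2	8000	T	C
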
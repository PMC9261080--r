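subject_id	rs1	rs2	rs3	rs4
P1	0	1	2	NA
P2	1	2	0	1
P3	2	0	1	2
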
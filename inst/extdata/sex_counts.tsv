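group	male	female
EOS	14	13
SB	8	16
HC	28	20
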
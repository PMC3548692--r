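category	score
frame shift	1.0
missense	0.9
start codon	0.85
UTR-3	0.6
UTR-5	0.6
near-gene-3	0.4
near-gene-5	0.4
intron	0.2
intergenic	0.1
unknown	0.1
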
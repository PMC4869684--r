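haplotype	frequency
GTATA	0.2327
GTGCG	0.2295
GCGCG	0.1608
GCATA	0.1295
ATATA	0.0866
ATGCG	0.0793
ACATA	0.0434
ACGCG	0.0259
ATGTA	0.0029
ATACA	0.0029
ACACA	0.0023
GTACA	0.0019
GTGTA	0.0017
GCGTA	0.0005
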
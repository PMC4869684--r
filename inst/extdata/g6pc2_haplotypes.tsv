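haplotype	frequency
CCAC	0.46
TCAG	0.29
CCAG	0.24
TCCG	0.006
CTAC	0.001
TCAC	0.001
CTAG	0.001
CCCG	0.001
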
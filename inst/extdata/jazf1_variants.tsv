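name	chr	pos	rsid	minor	major	maf
exm-rs10486567	7	27976563	rs10486567	A	G	0.2415
exm2270592	7	28039797	rs38523	C	T	0.3683
exm-rs864745	7	28180556	rs864745	G	A	0.4965
exm-rs1635852	7	28189411	rs1635852	C	T	0.4973
exm-rs849134	7	28196222	rs849134	G	A	0.4917
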
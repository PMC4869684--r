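name	chr	pos	rsid	minor	major	maf
exm-rs560887	2	169763148	rs560887	T	C	0.293
exm239664	2	169763262	rs138726309	T	C	0.0036
exm239667	2	169764141	rs2232323	C	A	0.0078
exm239672	2	169764176	rs492594	C	G	0.4553
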
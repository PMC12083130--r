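rsid	gene	significant
rs1042579	THBD	1
rs6025	F5	1
rs1799963	F2	0
rs6048	F9	0
rs1799808	PROC	0
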
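terminus	atom	x	y	z
N	N	-0.962	1.027	0.277
N	CA	0.094	-0.248	0.054
N	C	1.196	0.808	-0.222
C	N	22.383	0.165	-0.605
C	CA	23.498	-0.024	-0.02
C	C	24.781	-0.15	-0.674
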
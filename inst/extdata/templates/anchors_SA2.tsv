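terminus	atom	x	y	z
N	N	-0.821	1.077	0.129
N	CA	0.013	-0.265	-0.004
N	C	1.172	0.833	-0.095
C	N	22.229	0.165	-0.807
C	CA	23.513	0.019	-0.043
C	C	24.725	-0.189	-0.717
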
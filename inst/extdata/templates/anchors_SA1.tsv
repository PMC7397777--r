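terminus	atom	x	y	z
N	N	-1.046	0.841	-0.103
N	CA	-0.216	0.09	0.083
N	C	1.629	0.688	0.248
C	N	22.438	0.066	-0.611
C	CA	23.642	0.074	0.272
C	C	24.894	0.063	-1.085
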
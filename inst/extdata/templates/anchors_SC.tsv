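terminus	atom	x	y	z
N	N	-1.382	1.033	0.042
N	CA	-0.009	0.075	-0.102
N	C	1.213	0.791	-0.132
C	N	22.285	-0.018	-0.5
C	CA	23.505	-0.004	0.036
C	C	24.807	-0.398	-0.685
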
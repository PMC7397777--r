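terminus	atom	x	y	z
N	N	-1.02	0.804	0.022
N	CA	-0.201	-0.12	-0.151
N	C	1.212	0.619	-0.198
C	N	22.19	-0.015	-0.682
C	CA	23.273	-0.032	-0.14
C	C	24.884	-0.33	-0.878
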
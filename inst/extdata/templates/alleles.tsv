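allele	supertype
SYN-A01	SA1
SYN-A02	SA2
SYN-A03	SA1
SYN-B01	SB
SYN-B02	SB
SYN-C01	SC
HLA-A*02:01	SA1
HLA-A*24:02	SA2
HLA-B*07:02	SB
HLA-B*35:01	SB
HLA-C*04:01	SC
HLA-C*05:01	SC
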
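gene	cv
18S	0.054
ACT101	0.089
ACTB	0.188
ACT7	0.137
ACT11	0.071
TUA	0.132
TUB	0.152
GAPDH1	0.159
GAPDH2	0.075
MET	0.148
FBA	0.215
HIS	0.104
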
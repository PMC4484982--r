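gene	efficiency
18S	1.807
ACT101	1.901
ACTB	1.987
ACT7	1.908
ACT11	1.907
TUA	1.834
TUB	1.961
GAPDH1	1.920
GAPDH2	1.901
MET	1.910
FBA	1.902
HIS	2.047
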
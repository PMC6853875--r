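pd1_label,pd1_resseq,pdl1_label,pdl1_resseq
Y68,68,D122,122
Q75,75,D26,26
Q75,75,R125,125
A132,132,Q66,66
I134,134,Y56,56
I134,134,E58,58
I134,134,Y123,123
E136,136,R113,113
E136,136,Y123,123
E136,136,R125,125
N66,66,D122,122
Q75,75,I126,126
K78,78,T20,20
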
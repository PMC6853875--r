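water,pd1_label,pd1_resseq,pdl1_label,pdl1_resseq
HOH202,I134,134,Y56,56
HOH202,I134,134,E58,58
HOH203,N66,66,A121,121
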
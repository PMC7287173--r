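patient,fGt,fP,rsrReported
1,5,5,1.00
2,3,4,0.67
3,5,6,0.80
4,4,5,0.75
5,5,5,1.00
6,7,7,1.00
7,3,3,1.00
8,4,6,0.50
9,4,4,1.00
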
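patient,etGtMean,etGtSd,etPredMean,etPredSd,rmseUm,maeUm
1,56.06,2.05,65.02,0.76,9.13,8.95
2,49.20,1.50,58.19,1.77,9.28,8.98
3,78.90,3.83,62.50,2.75,8.90,8.68
4,82.47,2.63,87.00,1.90,5.75,4.62
5,71.30,3.83,83.65,3.02,13.29,12.90
6,71.43,2.40,77.90,1.99,7.30,6.61
7,92.12,3.37,106.00,1.20,14.40,13.87
8,76.12,1.67,85.42,0.76,9.70,9.29
9,85.16,2.94,98.69,1.18,14.10,13.52
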
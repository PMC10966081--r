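index,beta1,beta0,R,R2,SE,F
R1,0.86,-1.158,0.998,0.995,0.114,1689.506
RN1,1.28,1.032,0.997,0.995,0.118,1560.834
R12,0.918,-0.554,0.999,0.999,0.061,5839.737
RN12,1.117,0.519,0.999,0.999,0.063,5453.919
ABC,1.022,0.284,1,1,0.013,123210.473
GA,0.989,0.072,1,1,0.011,186557.243
M1,0.926,-1.259,1,0.999,0.051,8238.997
M2,0.86,-1.158,0.998,0.995,0.114,1689.506
HM,0.871,-2.461,0.998,0.996,0.099,2217.52
F,0.882,-1.965,0.999,0.997,0.084,3052.608
AZI,0.905,-1.692,0.999,0.998,0.065,5229.637
ReZG1,1.134,-0.362,0.999,0.998,0.074,3923.561
ReZG2,0.91,0.133,0.999,0.998,0.074,474.447
ReZG3,0.812,-2.367,0.995,0.991,0.159,872.398
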
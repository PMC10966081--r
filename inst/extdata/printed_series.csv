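table,kind,index,i,value
4,index,R1,1,22
4,index,R1,2,198
4,index,R1,3,542
4,index,R1,4,1054
4,index,R1,5,1734
4,index,R1,6,2582
4,index,R1,7,3598
4,index,R1,8,4782
4,index,R1,9,6134
4,index,R1,10,7654
4,index,R12,1,11.19
4,index,R12,2,72.64
4,index,R12,3,185.81
4,index,R12,4,350.69
4,index,R12,5,567.28
4,index,R12,6,835.58
4,index,R12,7,1155.59
4,index,R12,8,1527.33
4,index,R12,9,1950.77
4,index,R12,10,2425.92
4,index,RN12,1,3.39
4,index,RN12,2,11.47
4,index,RN12,3,24.54
4,index,RN12,4,42.57
4,index,RN12,5,65.59
4,index,RN12,6,93.58
4,index,RN12,7,126.55
4,index,RN12,8,164.49
4,index,RN12,9,207.41
4,index,RN12,10,255.31
5,index,ABC,1,4.46
5,index,ABC,2,19.44
5,index,ABC,3,44.93
5,index,ABC,4,80.91
5,index,ABC,5,127.38
5,index,ABC,6,184.36
5,index,ABC,7,251.83
5,index,ABC,8,329.8
5,index,ABC,9,418.27
5,index,ABC,10,517.23
5,index,GA,1,5.53
5,index,GA,2,27.29
5,index,GA,3,64.97
5,index,GA,4,118.56
5,index,GA,5,188.07
5,index,GA,6,273.5
5,index,GA,7,374.85
5,index,GA,8,492.11
5,index,GA,9,625.29
5,index,GA,10,774.39
5,index,M1,1,24
5,index,M1,2,148
5,index,M1,3,376
5,index,M1,4,708
5,index,M1,5,1144
5,index,M1,6,1684
5,index,M1,7,2328
5,index,M1,8,3076
5,index,M1,9,3928
5,index,M1,10,4884
5,index,M2,1,22
5,index,M2,2,198
5,index,M2,3,542
5,index,M2,4,1054
5,index,M2,5,1734
5,index,M2,6,2582
5,index,M2,7,3598
5,index,M2,8,4782
5,index,M2,9,6134
5,index,M2,10,7654
6,index,HM,1,100
6,index,HM,2,816
6,index,HM,3,2212
6,index,HM,4,4288
6,index,HM,5,7044
6,index,HM,6,10480
6,index,HM,7,14596
6,index,HM,8,19392
6,index,HM,9,24868
6,index,HM,10,31024
6,index,F,1,56
6,index,F,2,420
6,index,F,3,1128
6,index,F,4,2180
6,index,F,5,3576
6,index,F,6,5316
6,index,F,7,7400
6,index,F,8,9828
6,index,F,9,12600
6,index,F,10,15716
6,index,AZI,1,38.75
6,index,AZI,2,265.17
6,index,AZI,3,693.3
6,index,AZI,4,1323.16
6,index,AZI,5,2154.73
6,index,AZI,6,3188.02
6,index,AZI,7,4423.03
6,index,AZI,8,5859.75
6,index,AZI,9,7498.19
6,index,AZI,10,9338.35
6,index,ReZG1,1,7.33
6,index,ReZG1,2,23.66
6,index,ReZG1,3,49.99
6,index,ReZG1,4,86.33
6,index,ReZG1,5,132.66
6,index,ReZG1,6,188.99
6,index,ReZG1,7,255.33
6,index,ReZG1,8,331.66
6,index,ReZG1,9,417.99
6,index,ReZG1,10,514.33
7,index,ReZG2,1,5.23
7,index,ReZG2,2,35.69
7,index,ReZG2,3,91.86
7,index,ReZG2,4,173.74
7,index,ReZG2,5,281.34
7,index,ReZG2,6,414.66
7,index,ReZG2,7,573.68
7,index,ReZG2,8,758.43
7,index,ReZG2,9,968.88
7,index,ReZG2,10,1205.05
7,index,ReZG3,1,96
7,index,ReZG3,2,1128
7,index,ReZG3,3,3248
7,index,ReZG3,4,6456
7,index,ReZG3,5,10752
7,index,ReZG3,6,16136
7,index,ReZG3,7,22608
7,index,ReZG3,8,30168
7,index,ReZG3,9,38816
7,index,ReZG3,10,48552
8,entropy,R1,1,1.688
8,entropy,R1,2,3.2406
8,entropy,R1,3,4.1241
8,entropy,R1,4,4.7356
8,entropy,R1,5,5.2034
8,entropy,R1,6,5.5824
8,entropy,R1,7,5.9008
8,entropy,R1,8,6.1755
8,entropy,R1,9,6.4169
8,entropy,R1,10,6.6324
8,entropy,RN1,1,1.7045
8,entropy,RN1,2,3.1804
8,entropy,RN1,3,4.0644
8,entropy,RN1,4,4.6847
8,entropy,RN1,5,5.1603
8,entropy,RN1,6,5.5453
8,entropy,RN1,7,5.8685
8,entropy,RN1,8,6.1469
8,entropy,RN1,9,6.3913
8,entropy,RN1,10,6.6092
8,entropy,R12,1,1.7653
8,entropy,R12,2,3.3056
8,entropy,R12,3,4.17045
8,entropy,R12,4,4.7723
8,entropy,R12,5,5.2343
8,entropy,R12,6,5.6093
8,entropy,R12,7,5.925
8,entropy,R12,8,6.1976
8,entropy,R12,9,6.4374
8,entropy,R12,10,6.6516
8,entropy,RN12,1,1.7676
8,entropy,RN12,2,3.2975
8,entropy,RN12,3,4.1628
8,entropy,RN12,4,4.766
8,entropy,RN12,5,5.229
8,entropy,RN12,6,5.6048
8,entropy,RN12,7,5.9211
8,entropy,RN12,8,6.1942
8,entropy,RN12,9,6.4344
8,entropy,RN12,10,6.6488
9,entropy,ABC,1,1.7893
9,entropy,ABC,2,3.3304
9,entropy,ABC,3,4.1884
9,entropy,ABC,4,4.7865
9,entropy,ABC,5,5.2462
9,entropy,ABC,6,5.6196
9,entropy,ABC,7,5.9342
9,entropy,ABC,8,6.206
9,entropy,ABC,9,6.4451
9,entropy,ABC,10,6.6588
9,entropy,GA,1,1.7838
9,entropy,GA,2,3.3287
9,entropy,GA,3,4.1875
9,entropy,GA,4,4.7859
9,entropy,GA,5,5.2458
9,entropy,GA,6,5.6194
9,entropy,GA,7,5.934
9,entropy,GA,8,6.2058
9,entropy,GA,9,6.445
9,entropy,GA,10,6.65873
9,entropy,M1,1,1.7707
9,entropy,M1,2,3.3098
9,entropy,M1,3,4.1724
9,entropy,M1,4,4.7734
9,entropy,M1,5,5.235
9,entropy,M1,6,5.6098
9,entropy,M1,7,5.9253
9,entropy,M1,8,6.1978
9,entropy,M1,9,6.4376
9,entropy,M1,10,6.6516
9,entropy,M2,1,1.688
9,entropy,M2,2,3.2406
9,entropy,M2,3,4.1241
9,entropy,M2,4,4.7356
9,entropy,M2,5,5.2034
9,entropy,M2,6,5.5824
9,entropy,M2,7,5.9008
9,entropy,M2,8,6.1755
9,entropy,M2,9,6.4169
9,entropy,M2,10,6.6324
10,entropy,HM,1,1.713
10,entropy,HM,2,3.2527
10,entropy,HM,3,4.1295
10,entropy,HM,4,4.7385
10,entropy,HM,5,5.2051
10,entropy,HM,6,5.5833
10,entropy,HM,7,5.9013
10,entropy,HM,8,6.17566
10,entropy,HM,9,6.4168
10,entropy,HM,10,6.6321
10,entropy,F,1,1.7247
10,entropy,F,2,3.2617
10,entropy,F,3,4.1336
10,entropy,F,4,4.7406
10,entropy,F,5,5.2062
10,entropy,F,6,5.5838
10,entropy,F,7,5.9014
10,entropy,F,8,6.1755
10,entropy,F,9,6.4165
10,entropy,F,10,6.6316
10,entropy,AZI,1,1.728
10,entropy,AZI,2,3.2874
10,entropy,AZI,3,4.1566
10,entropy,AZI,4,4.761
10,entropy,AZI,5,5.2246
10,entropy,AZI,6,5.6008
10,entropy,AZI,7,5.9174
10,entropy,AZI,8,6.1906
10,entropy,AZI,9,6.431
10,entropy,AZI,10,6.6455
10,entropy,ReZG1,1,1.7633
10,entropy,ReZG1,2,3.2889
10,entropy,ReZG1,3,4.1574
10,entropy,ReZG1,4,4.7623
10,entropy,ReZG1,5,5.2265
10,entropy,ReZG1,6,5.6029
10,entropy,ReZG1,7,5.9197
10,entropy,ReZG1,8,6.193
10,entropy,ReZG1,9,6.4335
10,entropy,ReZG1,10,6.6481
11,entropy,ReZG2,1,1.7571
11,entropy,ReZG2,2,3.3009
11,entropy,ReZG2,3,4.1681
11,entropy,ReZG2,4,4.7709
11,entropy,ReZG2,5,5.2334
11,entropy,ReZG2,6,5.6087
11,entropy,ReZG2,7,5.9246
11,entropy,ReZG2,8,6.1973
11,entropy,ReZG2,9,6.4373
11,entropy,ReZG2,10,6.6515
11,entropy,ReZG3,1,1.5934
11,entropy,ReZG3,2,3.1255
11,entropy,ReZG3,3,4.0156
11,entropy,ReZG3,4,4.6311
11,entropy,ReZG3,5,5.1015
11,entropy,ReZG3,6,5.4822
11,entropy,ReZG3,7,5.8019
11,entropy,ReZG3,8,6.0775
11,entropy,ReZG3,9,6.3198
11,entropy,ReZG3,10,6.5358
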
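element,energy_kev,mu_rho_cm2_g
H,1,7.217
H,1.5,2.148
H,2,1.059
H,3,0.5612
H,4,0.4546
H,5,0.4193
H,6,0.4042
H,8,0.3914
H,10,0.3854
H,15,0.3764
H,20,0.3695
H,30,0.3570
H,40,0.3458
H,50,0.3355
H,60,0.3260
H,80,0.3091
H,100,0.2944
H,150,0.2651
H,200,0.2429
H,300,0.2112
H,400,0.1893
H,500,0.1729
C,1,2211
C,1.5,700.2
C,2,302.6
C,3,90.33
C,4,37.78
C,5,19.12
C,6,10.95
C,8,4.576
C,10,2.373
C,15,0.8071
C,20,0.4420
C,30,0.2562
C,40,0.2076
C,50,0.1871
C,60,0.1753
C,80,0.1610
C,100,0.1514
C,150,0.1347
C,200,0.1229
C,300,0.1066
C,400,0.09546
C,500,0.08715
N,1,3311
N,1.5,1083
N,2,476.9
N,3,145.6
N,4,61.47
N,5,31.33
N,6,17.98
N,8,7.563
N,10,3.879
N,15,1.236
N,20,0.6178
N,30,0.3066
N,40,0.2288
N,50,0.1980
N,60,0.1817
N,80,0.1639
N,100,0.1529
N,150,0.1353
N,200,0.1233
N,300,0.1068
N,400,0.09557
N,500,0.08719
O,1,4590
O,1.5,1549
O,2,694.9
O,3,217.1
O,4,93.15
O,5,47.90
O,6,27.70
O,8,11.63
O,10,5.952
O,15,1.836
O,20,0.8651
O,30,0.3779
O,40,0.2585
O,50,0.2132
O,60,0.1907
O,80,0.1678
O,100,0.1551
O,150,0.1361
O,200,0.1237
O,300,0.1070
O,400,0.09566
O,500,0.08729
Be,1,604.1
Be,1.5,179.7
Be,2,74.69
Be,3,21.27
Be,4,8.685
Be,5,4.369
Be,6,2.527
Be,8,1.124
Be,10,0.6466
Be,15,0.3070
Be,20,0.2251
Be,30,0.1792
Be,40,0.1640
Be,50,0.1554
Be,60,0.1493
Be,80,0.1401
Be,100,0.1328
Be,150,0.1190
Be,200,0.1089
Be,300,0.09463
Be,400,0.08471
Be,500,0.07739
Al,1,1185
Al,1.5,402.2
Al,1.5595,362.1
Al,1.5597,3957
Al,2,2263
Al,3,788.0
Al,4,360.5
Al,5,193.4
Al,6,115.3
Al,8,50.33
Al,10,26.23
Al,15,7.955
Al,20,3.441
Al,30,1.128
Al,40,0.5685
Al,50,0.3681
Al,60,0.2778
Al,80,0.2018
Al,100,0.1704
Al,150,0.1378
Al,200,0.1223
Al,300,0.1042
Al,400,0.09276
Al,500,0.08445
I,6,600
I,8,286
I,10,165
I,15,55.2
I,20,25.6
I,25,14.1
I,30,8.56
I,33.1693,6.553
I,33.1695,35.82
I,35,31.1
I,40,21.6
I,50,11.9
I,60,7.25
I,80,3.29
I,100,1.84
I,150,0.72
I,200,0.435
I,300,0.245
I,400,0.178
I,500,0.143
W,12.5,215
W,15,139
W,20,65.73
W,30,22.73
W,40,10.67
W,50,5.949
W,60,3.713
W,69.523,2.552
W,69.527,11.23
W,80,7.810
W,100,4.438
W,150,1.581
W,200,0.7844
W,300,0.3238
W,400,0.1925
W,500,0.1378
Air,1,3606
Air,1.5,1191
Air,2,527.9
Air,3,162.5
Air,4,77.88
Air,5,40.27
Air,6,23.41
Air,8,9.921
Air,10,5.120
Air,15,1.614
Air,20,0.7779
Air,30,0.3538
Air,40,0.2485
Air,50,0.2080
Air,60,0.1875
Air,80,0.1662
Air,100,0.1541
Air,150,0.1356
Air,200,0.1233
Air,300,0.1067
Air,400,0.09549
Air,500,0.08712
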
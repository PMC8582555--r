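# coarse placeholder 50 kVp spectrum (synthetic, not SpekCalc)
e_low_kev,e_high_kev,fluence
10,11,3.7619
11,12,3.3478
12,13,3
13,14,2.7037
14,15,2.4483
15,16,2.2258
16,17,2.0303
17,18,1.8571
18,19,1.7027
19,20,1.5641
20,21,1.439
21,22,1.3256
22,23,1.2222
23,24,1.1277
24,25,1.0408
25,26,0.9608
26,27,0.8868
27,28,0.8182
28,29,0.7544
29,30,0.6949
30,31,0.6393
31,32,0.5873
32,33,0.5385
33,34,0.4925
34,35,0.4493
35,36,0.4085
36,37,0.3699
37,38,0.3333
38,39,0.2987
39,40,0.2658
40,41,0.2346
41,42,0.2048
42,43,0.1765
43,44,0.1494
44,45,0.1236
45,46,0.0989
46,47,0.0753
47,48,0.0526
48,49,0.0309
49,50,0.0101
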
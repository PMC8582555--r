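# coarse placeholder 100 kVp spectrum (synthetic, not SpekCalc)
e_low_kev,e_high_kev,fluence
10,11,8.5238
11,12,7.6957
12,13,7
13,14,6.4074
14,15,5.8966
15,16,5.4516
16,17,5.0606
17,18,4.7143
18,19,4.4054
19,20,4.1282
20,21,3.878
21,22,3.6512
22,23,3.4444
23,24,3.2553
24,25,3.0816
25,26,2.9216
26,27,2.7736
27,28,2.6364
28,29,2.5088
29,30,2.3898
30,31,2.2787
31,32,2.1746
32,33,2.0769
33,34,1.9851
34,35,1.8986
35,36,1.8169
36,37,1.7397
37,38,1.6667
38,39,1.5974
39,40,1.5316
40,41,1.4691
41,42,1.4096
42,43,1.3529
43,44,1.2989
44,45,1.2472
45,46,1.1978
46,47,1.1505
47,48,1.1053
48,49,1.0619
49,50,1.0202
50,51,0.9802
51,52,0.9417
52,53,0.9048
53,54,0.8692
54,55,0.8349
55,56,0.8018
56,57,0.7699
57,58,0.7391
58,59,0.7094
59,60,0.6807
60,61,0.6529
61,62,0.626
62,63,0.6
63,64,0.5748
64,65,0.5504
65,66,0.5267
66,67,0.5038
67,68,0.4815
68,69,0.4599
69,70,0.4388
70,71,0.4184
71,72,0.3986
72,73,0.3793
73,74,0.3605
74,75,0.3423
75,76,0.3245
76,77,0.3072
77,78,0.2903
78,79,0.2739
79,80,0.2579
80,81,0.2422
81,82,0.227
82,83,0.2121
83,84,0.1976
84,85,0.1834
85,86,0.1696
86,87,0.1561
87,88,0.1429
88,89,0.1299
89,90,0.1173
90,91,0.105
91,92,0.0929
92,93,0.0811
93,94,0.0695
94,95,0.0582
95,96,0.0471
96,97,0.0363
97,98,0.0256
98,99,0.0152
99,100,0.005
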
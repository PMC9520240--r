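age,sex,qx
30,male,0.000816
31,male,0.00089
32,male,0.000971
33,male,0.001059
34,male,0.001155
35,male,0.00126
36,male,0.001374
37,male,0.001499
38,male,0.001635
39,male,0.001784
40,male,0.001946
41,male,0.002122
42,male,0.002315
43,male,0.002525
44,male,0.002754
45,male,0.003004
46,male,0.003277
47,male,0.003574
48,male,0.003899
49,male,0.004252
50,male,0.004638
51,male,0.005058
52,male,0.005517
53,male,0.006017
54,male,0.006562
55,male,0.007156
56,male,0.007804
57,male,0.008511
58,male,0.009281
59,male,0.01012
60,male,0.011035
61,male,0.012032
62,male,0.013118
63,male,0.014302
64,male,0.015592
65,male,0.016997
66,male,0.018527
67,male,0.020194
68,male,0.02201
69,male,0.023986
70,male,0.026138
71,male,0.028479
72,male,0.031027
73,male,0.0338
74,male,0.036815
75,male,0.040093
76,male,0.043657
77,male,0.047529
78,male,0.051736
79,male,0.056303
80,male,0.061261
81,male,0.06664
82,male,0.072473
83,male,0.078794
84,male,0.08564
85,male,0.093051
86,male,0.101067
87,male,0.109731
88,male,0.119088
89,male,0.129182
90,male,0.140063
91,male,0.151777
92,male,0.164374
93,male,0.177903
94,male,0.192412
95,male,0.207948
96,male,0.224556
97,male,0.242276
98,male,0.261145
99,male,0.281194
100,male,0.302446
30,female,0.000411
31,female,0.00045
32,female,0.000494
33,female,0.000541
34,female,0.000593
35,female,0.000651
36,female,0.000713
37,female,0.000782
38,female,0.000857
39,female,0.00094
40,female,0.00103
41,female,0.00113
42,female,0.001238
43,female,0.001358
44,female,0.001488
45,female,0.001632
46,female,0.001789
47,female,0.001961
48,female,0.00215
49,female,0.002356
50,female,0.002583
51,female,0.002832
52,female,0.003104
53,female,0.003403
54,female,0.00373
55,female,0.004089
56,female,0.004482
57,female,0.004913
58,female,0.005385
59,female,0.005903
60,female,0.006469
61,female,0.007091
62,female,0.007771
63,female,0.008517
64,female,0.009334
65,female,0.010229
66,female,0.011209
67,female,0.012282
68,female,0.013458
69,female,0.014745
70,female,0.016155
71,female,0.017698
72,female,0.019386
73,female,0.021235
74,female,0.023257
75,female,0.025469
76,female,0.027889
77,female,0.030535
78,female,0.033428
79,female,0.036589
80,female,0.040044
81,female,0.043817
82,female,0.047937
83,female,0.052433
84,female,0.057338
85,female,0.062687
86,female,0.068516
87,female,0.074865
88,female,0.081776
89,female,0.089294
90,female,0.097466
91,female,0.106341
92,female,0.115971
93,female,0.12641
94,female,0.137713
95,female,0.149937
96,female,0.163141
97,female,0.177381
98,female,0.192715
99,female,0.209198
100,female,0.226883
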
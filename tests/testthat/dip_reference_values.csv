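case,dip
1,0.178624174824
2,0.094155844156
3,0.032648927255
4,0.067073170732
5,0.116510483341
6,0.178616189945
7,0.073529411765
8,0.040458960709
9,0.075471698113
10,0.042884803061
11,0.176778960782
12,0.097222222222
13,0.054988753869
14,0.045454545455
15,0.064797487979
16,0.186711500018
17,0.070833333333
18,0.046249497623
19,0.150000000000
20,0.082778720489
21,0.157228803194
22,0.178571428571
23,0.032736031843
24,0.062500000000
25,0.061467686746
26,0.187291025929
27,0.090909090909
28,0.091257531655
29,0.066666666667
30,0.095608929198
31,0.205232708934
32,0.078125000000
33,0.085046491732
34,0.077777777778
35,0.036673300174
36,0.184703048854
37,0.092592592593
38,0.032429541729
39,0.062500000000
40,0.033154616611
41,0.186637842567
42,0.142857142857
43,0.047453573593
44,0.086538461538
45,0.040928021006
46,0.183287877467
47,0.111111111111
48,0.026743379009
49,0.070175438596
50,0.059992419626
51,0.172020552040
52,0.096014492754
53,0.032619912878
54,0.121212121212
55,0.032867022871
56,0.178313019260
57,0.097222222222
58,0.043085351944
59,0.084183673469
60,0.060228566855
61,0.176794957572
62,0.090909090909
63,0.044758282310
64,0.072727272727
65,0.051932102175
66,0.176843466436
67,0.075000000000
68,0.055110902809
69,0.069444444444
70,0.082744555612
71,0.173246091411
72,0.052083333333
73,0.034906890380
74,0.078125000000
75,0.056344050912
76,0.198496589016
77,0.096666666667
78,0.133322369718
79,0.080000000000
80,0.058266282959
81,0.174981236686
82,0.070000000000
83,0.058232519507
84,0.060344827586
85,0.075376767403
86,0.158958703506
87,0.075000000000
88,0.079785647019
89,0.056603773585
90,0.048273571175
91,0.153807179919
92,0.076666666667
93,0.033943228893
94,0.072948328267
95,0.043579626539
96,0.166062788293
97,0.071428571429
98,0.046836390548
99,0.070833333333
100,0.045787842434
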
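compound_id,ic50_uM,test_2d,test_3d
1,15.41,FALSE,NA
2,20.35,TRUE,NA
3,17.85,FALSE,NA
4,18.98,FALSE,NA
5,18.0,TRUE,NA
6,6.41,TRUE,NA
7,29.87,FALSE,NA
8,8.05,FALSE,NA
9,18.38,FALSE,NA
10,7.55,FALSE,NA
11,8.65,TRUE,NA
12,23.65,FALSE,NA
13,20.97,FALSE,NA
14,0.76,FALSE,NA
15,27.74,TRUE,NA
16,9.27,FALSE,NA
17,16.02,TRUE,NA
18,24.11,FALSE,NA
19,10.42,TRUE,NA
20,19.11,FALSE,NA
21,28.17,TRUE,NA
22,34.12,FALSE,NA
23,3.01,FALSE,NA
24,3.18,TRUE,NA
25,4.20,FALSE,NA
26,3.33,FALSE,NA
27,3.56,FALSE,NA
28,40.42,FALSE,NA
29,2.88,FALSE,NA
30,6.18,FALSE,NA
31,5.9,FALSE,NA
32,7.33,FALSE,NA
33,8.13,FALSE,NA
34,11.48,FALSE,NA
35,8.33,FALSE,NA
36,7.59,FALSE,NA
37,20.92,FALSE,NA
38,3.93,FALSE,NA
39,5.44,FALSE,NA
40,4.60,TRUE,NA
41,10.27,FALSE,NA
42,13.23,FALSE,NA
43,23.23,FALSE,NA
44,11.43,FALSE,NA
45,2.22,FALSE,NA
46,8.43,FALSE,NA
47,9.09,FALSE,NA
48,4.20,FALSE,NA
49,5.39,FALSE,NA
50,4.42,FALSE,NA
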
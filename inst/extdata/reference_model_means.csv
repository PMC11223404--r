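model_number,updating,shifting,inhibition,cycles,mean_pe,sd_pe,label
1,very_poor,poor,very_poor,20,43.10,9.03,CT+
1,very_poor,poor,very_poor,40,24.40,7.45,CT+
1,very_poor,poor,very_poor,60,17.05,5.20,CT+
2,poor,poor,very_poor,20,25.65,6.05,CT+
2,poor,poor,very_poor,40,16.85,6.86,CT+
2,poor,poor,very_poor,60,15.20,5.06,"LT, CT"
3,medium,poor,very_poor,20,25.80,7.92,CT+
3,medium,poor,very_poor,40,14.80,5.46,"LT, CT"
3,medium,poor,very_poor,60,16.10,7.20,CT+
4,high,poor,very_poor,20,28.05,7.06,CT+
4,high,poor,very_poor,40,14.75,7.16,"LT, CT"
4,high,poor,very_poor,60,15.85,5.37,"LT, CT"
5,very_poor,medium,very_poor,20,25.15,3.53,CT+
5,very_poor,medium,very_poor,40,11.50,2.54,LT-
5,very_poor,medium,very_poor,60,10.20,1.32,LT-
6,very_poor,medium,poor,20,15.65,2.48,"LT, CT"
6,very_poor,medium,poor,40,7.00,1.30,LT-
6,very_poor,medium,poor,60,3.90,1.33,LT-
7,very_poor,medium,medium,20,10.00,2.10,LT-
7,very_poor,medium,medium,40,4.00,1.59,LT-
7,very_poor,medium,medium,60,1.95,1.67,LT-
8,very_poor,medium,high,20,6.80,2.50,LT-
8,very_poor,medium,high,40,2.45,1.50,LT-
8,very_poor,medium,high,60,2.00,1.23,LT-
9,very_poor,high,very_poor,20,23.10,3.28,CT+
9,very_poor,high,very_poor,40,11.60,2.33,LT-
9,very_poor,high,very_poor,60,10.80,1.64,LT-
10,very_poor,high,poor,20,15.60,5.47,"LT, CT"
10,very_poor,high,poor,40,6.65,1.98,LT-
10,very_poor,high,poor,60,3.10,1.68,LT-
11,very_poor,high,medium,20,9.60,1.88,LT-
11,very_poor,high,medium,40,3.20,1.61,LT-
11,very_poor,high,medium,60,2.45,1.39,LT-
12,very_poor,high,high,20,7.35,1.69,LT-
12,very_poor,high,high,40,2.45,1.82,LT-
12,very_poor,high,high,60,2.00,1.65,LT-
13,very_poor,poor,poor,20,17.65,4.82,CT+
13,very_poor,poor,poor,40,10.75,5.65,LT-
13,very_poor,poor,poor,60,8.65,4.40,LT-
14,very_poor,poor,medium,20,15.50,5.86,"LT, CT"
14,very_poor,poor,medium,40,6.80,5.21,LT-
14,very_poor,poor,medium,60,5.80,4.09,LT-
15,very_poor,poor,high,20,8.65,2.83,LT-
15,very_poor,poor,high,40,7.35,5.88,LT-
15,very_poor,poor,high,60,8.20,8.48,LT-
16,poor,medium,very_poor,20,28.30,6.89,CT+
16,poor,medium,very_poor,40,11.15,1.63,LT-
16,poor,medium,very_poor,60,9.80,2.07,LT-
17,medium,medium,very_poor,20,21.60,3.60,CT+
17,medium,medium,very_poor,40,9.80,1.54,LT-
17,medium,medium,very_poor,60,10.50,1.91,LT-
18,high,medium,very_poor,20,20.40,2.56,CT+
18,high,medium,very_poor,40,9.75,1.68,LT-
18,high,medium,very_poor,60,10.15,1.84,LT-
19,poor,high,very_poor,20,22.40,3.17,CT+
19,poor,high,very_poor,40,10.75,2.07,LT-
19,poor,high,very_poor,60,9.70,1.53,LT-
20,medium,high,very_poor,20,22.40,3.02,CT+
20,medium,high,very_poor,40,10.35,1.38,LT-
20,medium,high,very_poor,60,10.45,1.19,LT-
21,high,high,very_poor,20,22.30,2.92,CT+
21,high,high,very_poor,40,10.90,1.62,LT-
21,high,high,very_poor,60,9.80,2.02,LT-
22,poor,poor,poor,20,15.90,6.72,"LT, CT"
22,poor,poor,poor,40,8.85,4.33,LT-
22,poor,poor,poor,60,7.10,4.93,LT-
23,poor,poor,medium,20,12.45,4.83,LT-
23,poor,poor,medium,40,8.50,5.74,LT-
23,poor,poor,medium,60,4.55,2.93,LT-
24,poor,poor,high,20,10.05,4.65,LT-
24,poor,poor,high,40,6.25,5.10,LT-
24,poor,poor,high,60,6.70,4.61,LT-
25,poor,medium,poor,20,11.15,1.76,LT-
25,poor,medium,poor,40,7.50,1.19,LT-
25,poor,medium,poor,60,1.45,0.999,LT-
26,poor,medium,medium,20,7.55,1.50,LT-
26,poor,medium,medium,40,0.900,0.788,LT-
26,poor,medium,medium,60,0.050,0.224,LT-
27,poor,medium,high,20,4.60,2.06,LT-
27,poor,medium,high,40,0.450,0.605,LT-
27,poor,medium,high,60,0,0,LT-
28,poor,high,poor,20,12.15,1.57,LT-
28,poor,high,poor,40,7.45,0.999,LT-
28,poor,high,poor,60,1.60,0.940,LT-
29,poor,high,medium,20,7.75,1.25,LT-
29,poor,high,medium,40,0.900,1.29,LT-
29,poor,high,medium,60,0.050,0.223,LT-
30,poor,high,high,20,4.90,1.74,LT-
30,poor,high,high,40,0.350,0.489,LT-
30,poor,high,high,60,0,0,LT-
31,medium,poor,poor,20,16.05,6.92,CT+
31,medium,poor,poor,40,8.80,4.37,LT-
31,medium,poor,poor,60,6.45,6.24,LT-
32,medium,poor,medium,20,10.80,5.60,LT-
32,medium,poor,medium,40,6.89,5.89,LT-
32,medium,poor,medium,60,6.15,3.60,LT-
33,medium,poor,high,20,5.95,3.82,LT-
33,medium,poor,high,40,5.90,3.67,LT-
33,medium,poor,high,60,7.45,9.13,LT-
34,medium,medium,poor,20,9.15,1.90,LT-
34,medium,medium,poor,40,7.80,1.51,LT-
34,medium,medium,poor,60,0.100,0.308,LT-
35,medium,medium,medium,20,6.60,0.883,LT-
35,medium,medium,medium,40,0.100,0.308,LT-
35,medium,medium,medium,60,0,0,LT-
36,medium,medium,high,20,2.40,1.35,LT-
36,medium,medium,high,40,0,0,LT-
36,medium,medium,high,60,0,0,LT-
37,medium,high,poor,20,8.95,2.04,LT-
37,medium,high,poor,40,7.45,1.32,LT-
37,medium,high,poor,60,0.100,0.308,LT-
38,medium,high,medium,20,7.55,1.19,LT-
38,medium,high,medium,40,0.150,0.366,LT-
38,medium,high,medium,60,0,0,LT-
39,medium,high,high,20,1.95,1.23,LT-
39,medium,high,high,40,0,0,LT-
39,medium,high,high,60,0,0,LT-
40,high,poor,poor,20,16.60,4.78,CT+
40,high,poor,poor,40,9.05,7.70,LT-
40,high,poor,poor,60,6.35,4.22,LT-
41,high,poor,medium,20,11.05,5.12,LT-
41,high,poor,medium,40,8.35,7.50,LT-
41,high,poor,medium,60,6.55,4.26,LT-
42,high,poor,high,20,7.90,4.05,LT-
42,high,poor,high,40,10.35,7.12,LT-
42,high,poor,high,60,7.95,5.11,LT-
43,high,medium,poor,20,16.10,4.31,CT+
43,high,medium,poor,40,9.85,3.08,LT-
43,high,medium,poor,60,6.75,4.14,LT-
44,high,medium,medium,20,7.60,1.76,LT-
44,high,medium,medium,40,0.400,0.503,LT-
44,high,medium,medium,60,0.200,0.616,LT-
45,high,medium,high,20,4.35,1.78,LT-
45,high,medium,high,40,0.550,0.605,LT-
45,high,medium,high,60,0,0,LT-
46,high,high,poor,20,8.10,1.59,LT-
46,high,high,poor,40,7.35,1.14,LT-
46,high,high,poor,60,0,0,LT-
47,high,high,medium,20,6.50,0.889,LT-
47,high,high,medium,40,0,0,LT-
47,high,high,medium,60,0,0,LT-
48,high,high,high,20,1.30,1.30,LT-
48,high,high,high,40,0,0,LT-
48,high,high,high,60,0.050,0.223,LT-
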
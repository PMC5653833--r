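patient,age,gender,epilepsy,nights,intervals,trt_intervals,trt_nights,ripple_resected,fr_resected,frandr_resected,ilae,followup_months
1,25,M,TLE,4,28,0.99,1.00,N,N,Y,1,12
2,33,M,TLE,2,13,1.00,1.00,Y,Y,Y,1,29
3,20,F,TLE,5,39,0.78,1.00,N,Y,Y,1,13
4,20,F,TLE,6,34,1.00,1.00,N,Y,Y,1,41
5,40,M,TLE,5,35,0.94,1.00,Y,Y,Y,1,14
6,48,M,TLE,5,35,0.98,1.00,Y,Y,Y,1,11
7,25,M,TLE,1,1,,,Y,Y,Y,3,42
8,21,F,TLE,2,16,0.67,1.00,Y,Y,Y,3,15
9,52,M,TLE,2,12,1.00,1.00,Y,Y,Y,5,46
10,37,M,ETE,1,6,1.00,,N,Y,Y,1,36
11,36,M,ETE,3,19,1.00,1.00,Y,Y,Y,1,37
12,49,M,ETE,4,25,0.53,0.67,Y,N,Y,1,25
13,17,M,ETE,2,16,0.75,1.00,N,N,Y,1,25
14,46,F,ETE,2,13,0.97,1.00,Y,Y,Y,1,10
15,31,F,ETE,4,28,0.32,0.33,Y,N,Y,1,25
16,17,F,ETE,2,17,1.00,1.00,N,Y,Y,1,19
17,30,M,ETE,1,1,,,Y,Y,N,5,45
18,40,M,ETE,1,5,1.00,,N,Y,N,5,30
19,38,M,ETE,2,13,0.36,0.00,N,N,N,6,11
20,17,M,ETE,4,29,0.23,1.00,N,N,N,5,16
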
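rec,subj,dataset,st_h,se,tne,ahi,timetable,uncertain
1,S1,apnea,6.01,0.72,21,3.49,NA,TRUE
2,S2,apnea,9.66,0.77,145,15.01,NA,FALSE
3,S3,apnea,8.98,0.95,368,40.99,NA,TRUE
4,S4,apnea,8.74,0.42,2,0.23,NA,FALSE
5,S5,apnea,7.64,0.44,1,0.13,NA,FALSE
6,S6,apnea,8.87,0.66,454,50.63,NA,FALSE
7,S7,apnea,7.22,0.63,13,1.80,NA,FALSE
8,S8,apnea,8.34,0.59,6,0.72,NA,FALSE
9,S9,apnea,9.65,0.68,5,0.52,NA,FALSE
10,S10,apnea,6.18,0.46,196,31.74,NA,FALSE
11,S11,apnea,6.61,0.61,345,52.21,NA,FALSE
12,S12,apnea,6.49,0.53,180,27.75,NA,FALSE
13,S13,apnea,7.69,0.58,99,12.87,NA,TRUE
14,S14,apnea,9.05,0.68,162,17.90,NA,FALSE
15,S15,apnea,7.32,0.63,161,22.00,NA,TRUE
16,S16,apnea,11.17,0.64,109,9.76,NA,FALSE
17,S17,apnea,6.79,0.38,319,46.97,NA,FALSE
18,S18,apnea,8.56,0.90,39,4.56,NA,FALSE
19,S19,apnea,8.18,0.87,27,3.30,NA,FALSE
20,S20,apnea,7.02,0.77,161,22.92,NA,FALSE
21,S21,apnea,8.40,0.91,1,0.12,NA,FALSE
22,S22,apnea,5.73,0.80,34,5.93,NA,FALSE
23,S23,shift_work,4.34,0.95,NA,NA,D,FALSE
24,S23,shift_work,9.00,0.83,NA,NA,N,FALSE
25,S24,shift_work,3.90,0.84,NA,NA,D,FALSE
26,S24,shift_work,9.83,0.85,NA,NA,N,FALSE
27,S25,shift_work,4.94,0.85,NA,NA,D,FALSE
28,S25,shift_work,8.36,0.69,NA,NA,N,FALSE
29,S26,shift_work,4.06,0.69,NA,NA,D,FALSE
30,S26,shift_work,8.37,0.89,NA,NA,N,FALSE
31,S27,shift_work,4.89,0.86,NA,NA,D,FALSE
32,S27,shift_work,9.05,0.83,NA,NA,N,FALSE
33,S28,shift_work,5.54,0.94,NA,NA,D,FALSE
34,S28,shift_work,8.46,0.95,NA,NA,N,FALSE
35,S29,shift_work,5.25,0.93,NA,NA,D,FALSE
36,S29,shift_work,8.68,0.75,NA,NA,N,FALSE
37,S30,shift_work,4.13,0.93,NA,NA,D,FALSE
38,S30,shift_work,8.09,0.90,NA,NA,N,FALSE
39,S31,shift_work,4.60,0.86,NA,NA,D,FALSE
40,S31,shift_work,9.23,0.85,NA,NA,N,FALSE
41,S32,shift_work,4.80,0.79,NA,NA,D,FALSE
42,S32,shift_work,7.86,0.92,NA,NA,N,FALSE
43,S33,shift_work,5.21,0.47,NA,NA,D,FALSE
44,S33,shift_work,9.52,0.71,NA,NA,N,FALSE
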
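patient_no,cohort,group,sex,age,primary_site,differentiation,t_stage,n_stage,stage,g7s_percent,g7nl_grade,prediction_score,regimen,response
1,learning,R,F,61,Mandibula,Grade 2,T4,N1,4A,29,2,-2.78,PF + S/R,NC
2,learning,R,M,60,Maxillary sinus,Grade 3,T3,N2c,4C,0,0,-1.97,P/R,NC
3,learning,R,M,50,Floor of mouth,Grade 2,T3,N2b,4A,45.5,2,-1.82,S/R,NC
4,learning,R,M,57,Tongue,Grade 1,T2,N1,3,48.4,2,-1.65,S/R,NC
5,learning,R,M,79,Tongue,Grade 2,T3,N1,3,48.4,2,-1.65,S/R,NC
6,learning,R,M,32,Tongue,Grade 1,T2,N2b,4A,31.5,1,-1.38,S/R,NC
7,learning,R,M,57,Tongue,Grade 1,T3,N2b,4A,57.7,2,-1.10,PF + S/R,PD
8,learning,R,M,68,Mandibula,Grade 2,T4,N2b,4A,44.9,1,-0.61,PF,NC
9,learning,R,M,47,Tongue,Grade 2,T2,N0,2,46.6,1,-0.51,PF,NC
10,learning,S,M,72,Floor of mouth,Grade 2,T3,N2c,4A,72.5,2,-0.25,S/R,PR
11,learning,S,M,50,Tongue,Grade 1,T2,N0,2,34.6,0,0.04,S,PR
12,learning,S,M,82,Tongue,Grade 1,T2,N0,2,56.8,1,0.09,S,PR
13,learning,S,M,59,Tongue,Grade 2,T3,N0,3,61.6,0,1.61,S/R,PR
14,learning,S,M,61,Tongue,Grade 1,T2,N0,2,66.5,0,1.90,S,PR
15,learning,S,M,68,Lower gingiva,Grade 1,T2,N0,2,66.6,0,1.90,S/R,PR
16,learning,S,M,76,Lower gingiva,Grade 1,T2,N2b,4A,78.7,0,2.60,S,PR
17,learning,S,M,29,Tongue,Grade 2,T2,N0,2,80.4,0,2.70,S/R,PR
18,learning,S,M,53,Lower gingiva,Grade 1,T2,N1,3,83.3,0,2.87,S,PR
19,test,R,M,58,Mandibula,Grade 2,T4,N2b,4A,24.1,2,-3.06,S,NC
20,test,R,M,70,Floor of mouth,Grade 2,T2,N2c,4A,4.53,1,-2.95,R,NC
21,test,R,M,57,Maxillary sinus,Grade 2,T4,N1,4B,11.4,1,-2.55,P/R,NC
22,test,R,F,66,Maxillary sinus,Grade 2,T3,N2b,4A,12.7,1,-2.47,S/R,NC
23,test,R,M,45,Tongue,Grade 3,T3,N2b,4A,34.4,2,-2.46,PF,NC
24,test,R,M,60,Tongue,Grade 2,T4,N2c,4A,35.3,2,-2.41,S,NC
25,test,R,F,81,Lower gingiva,Grade 3,T4,N0,4A,16.6,1,-2.25,R,NC
26,test,R,F,72,Buccal mucosa,Grade 1,T4,N2b,4A,0,0,-1.97,R,NC
27,test,R,M,67,Upper gingiva,Grade 3,T2,N1,3,0.6,0,-1.93,S,NC
28,test,R,M,53,Soft palate,Grade 3,T4,N1,4A,8.14,0,-1.50,R,NC
29,test,R,M,59,Buccal mucosa,Grade 2,T4,N2b,4A,31.6,1,-1.38,R,NC
30,test,R,M,53,Mandibula,Grade 1,T4,N2b,4A,33.4,1,-1.27,R,NC
31,test,R,M,68,Mandibula,Grade 2,T4,N2b,4A,56.1,2,-1.20,S,NC
32,test,R,F,54,Tongue,Grade 2,T2,N2b,4A,37,1,-1.06,S,NC
33,test,R,F,52,Lower gingiva,Grade 2,T4,N2c,4A,60.8,2,-0.93,S,NC
34,test,R,M,61,Retromolar trigone,Grade 1,T4,N1,4A,40.7,1,-0.85,S,NC
35,test,R,M,41,Tongue,Grade 3,T2,N2c,4A,20.2,0,-0.79,R,NC
36,test,R,M,66,Mandibula,Grade 1,T4,N2b,4A,43,1,-0.72,S,NC
37,test,R,M,74,Lower gingiva,Grade 2,T4,N2b,4A,68,2,-0.51,S,NC
38,test,R,M,69,Tongue,Grade 2,T3,N2b,4A,25.8,0,-0.47,PF,NC
39,test,R,M,57,Mandibula,Grade 1,T4,N0,4A,31.8,0,-0.12,R,NC
40,test,R,M,64,Tongue,Grade 2,T3,N2c,4A,75,2,-0.10,PF,NC
41,test,R,M,62,Maxila,Grade 2,T4,N1,4A,33,0,-0.05,S/R,NC
42,test,R,M,57,Tongue,Grade 2,T2,N0,2,33.1,0,-0.04,S/R,NC
43,test,R,M,64,Tongue,Grade 2,T3,N2b,4A,72.4,1,0.99,S,NC
44,test,S,M,57,Maxillary sinus,Grade 2,T3,N0,3,0.7,2,-4.42,P/R,PR
45,test,S,M,52,Lower gingiva,Grade 2,T2,N2b,4A,1.35,2,-4.38,S/R,PR
46,test,S,M,55,Tongue,Grade 3,T3,N2b,4A,6.63,1,-2.83,PF,PR
47,test,S,M,74,Upper gingiva,Grade 3,T4,N2b,4A,9.94,1,-2.64,S/R,PR
48,test,S,M,62,Tongue,Grade 3,T3,N0,3,10.9,1,-2.58,S/R,PR
49,test,S,M,71,Buccal mucosa,Grade 3,T3,N2b,4B,39.9,2,-2.14,PF,PR
50,test,S,F,76,Upper gingiva,Grade 2,T4,N0,4A,0,0,-1.97,S/R,PR
51,test,S,F,52,Tongue,Grade 3,T3,N0,3,2.1,0,-1.85,S/R,PR
52,test,S,M,50,Tongue,Grade 1,T2,N0,2,6.2,0,-1.61,S/R,PR
53,test,S,M,49,Tongue,Grade 2,T3,N1,3,27.9,1,-1.60,PF,PR
54,test,S,M,48,Lower gingiva,Grade 1,T4,N0,4A,31.1,1,-1.41,S/R,PR
55,test,S,M,62,Lower gingiva,Grade 2,T3,N2b,4A,33.1,1,-1.29,S/R,PR
56,test,S,M,58,Floor of mouth,Grade 2,T2,N2c,4A,11.9,0,-1.28,R,PR
57,test,S,M,61,Upper gingiva,Grade 3,T4,N0,4A,12.2,0,-1.26,P/R,PR
58,test,S,M,59,Floor of mouth,Grade 2,T4,N2c,4A,33.7,1,-1.26,PF,PR
59,test,S,F,67,Tongue,Grade 2,T2,N2c,4A,34.8,1,-1.19,PF,PR
60,test,S,F,64,Upper gingiva,Grade 2,T3,N0,3,37.1,1,-1.06,S/R,PR
61,test,S,M,58,Lower gingiva,Grade 2,T3,N1,3,59,2,-1.03,S/R,PR
62,test,S,M,54,Lower gingiva,Grade 2,T2,N2b,4A,16.7,0,-1.00,S/R,PR
63,test,S,M,69,Tongue,Grade 2,T3,N0,3,20.8,0,-0.76,S/R,PR
64,test,S,M,65,Tongue,Grade 1,T3,N0,3,26.5,0,-0.43,PF,PR
65,test,S,F,40,Tongue,Grade 2,T2,N2b,4A,27.9,0,-0.35,S/R,PR
66,test,S,M,54,Lower gingiva,Grade 2,T4,N0,4A,28.3,0,-0.32,R,PR
67,test,S,M,55,Tongue,Grade 1,T3,N1,3,30.9,0,-0.18,S/R,PR
68,test,S,M,59,Floor of mouth,Grade 2,T2,N0,2,52.3,1,-0.17,S/R,PR
69,test,S,M,67,Floor of mouth,Grade 2,T4,N1,4A,31.1,0,-0.16,S/R,PR
70,test,S,F,64,Lower gingiva,Grade 1,T4,N1,4A,35.6,0,0.10,S/R,PR
71,test,S,M,65,Tongue,Grade 1,T3,N1,3,80,2,0.19,PF,PR
72,test,S,M,66,Floor of mouth,Grade 2,T3,N0,3,60.7,1,0.31,PF,PR
73,test,S,M,65,Retromolar trigone,Grade 2,T2,N0,2,41.4,0,0.44,R,PR
74,test,S,M,75,Upper gingiva,Grade 3,T4,N2c,4A,41.4,0,0.44,S/R,PR
75,test,S,F,62,Maxila,Grade 1,T4,N0,4A,42.6,0,0.51,PF/R,PR
76,test,S,F,52,Tongue,Grade 2,T2,N0,2,43.1,0,0.53,S/R,PR
77,test,S,M,59,Tongue,Grade 1,T3,N2c,4A,47,0,0.76,R,PR
78,test,S,M,48,Tongue,Grade 2,T3,N2b,4A,51.5,0,1.03,PF,PR
79,test,S,M,62,Buccal mucosa,Grade 2,T2,N0,2,52.8,0,1.10,S/R,PR
80,test,S,F,46,Tongue,Grade 2,T3,N0,3,54.3,0,1.18,S/R,PR
81,test,S,M,45,Lower gingiva,Grade 1,T4,N1,4A,54.4,0,1.19,S/R,PR
82,test,S,M,45,Floor of mouth,Grade 1,T2,N0,2,55.2,0,1.24,S/R,CR
83,test,S,M,56,Tongue,Grade 3,T3,N0,3,55.9,0,1.28,S/R,PR
84,test,S,F,62,Lower Gingiva,Grade 2,T3,N0,3,60.2,0,1.53,R,PR
85,test,S,M,58,Soft palate,Grade 2,T3,N0,3,69.9,0,2.09,S/R,PR
86,test,S,M,68,Lower gingiva,Grade 1,T4,N0,4A,71.6,0,2.19,S/R,PR
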
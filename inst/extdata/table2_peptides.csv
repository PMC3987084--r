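peak_id,mz,rt_min,charge,ratio_rs,accession,protein,mascot_score,peptide_seq,r_mean,r_sd,s_mean,s_sd
4722,725.7,55.3,3,0.47,P31947,14-3-3 protein sigma,62.41,TTFDEAMADLHTLSEDSYK,1070,538,2263,846
6326,776.4,55.3,2,0.48,P04083,Annexin A1,62.79,GTDVNVFNTILTTR,2782,1387,5762,3858
25210,574.0,38.9,3,0.25,P22528,Cornifin-B,51.67,QPCTPPPQLQQQQVK,71,83,282,293
1294,726.7,57.3,3,0.48,P15924,Desmoplakin,129.32,FLEFQYLTGGLVDPEVHGR,1805,1148,3765,2017
2504,627.8,50.5,2,0.39,P15924,Desmoplakin,60.97,AITGFDDPFSGK,958,348,2460,938
3011,843.5,50.8,2,0.45,P15924,Desmoplakin,116.28,ITNLTQQLEQASIVK,846,351,1889,751
3292,752.1,55.7,3,0.48,P15924,Desmoplakin,105.46,LLEAQIASGGVVDPVNSVFLPK,1109,568,2304,930
1196,677.4,52.3,2,0.47,P12724,Eosinophil cationic protein,63.88,YPVVPVHLDTTI,1297,443,2786,1933
599,494.6,44.4,3,0.45,P47929,Galectin-7,52.89,SSLPEGIRPGTVLR,2730,1558,6018,2658
1181,619.8,43.9,2,0.47,P47929,Galectin-7,87.57,LDTSEVVFNSK,1763,993,3764,1639
31232,593.6,48.5,2,0.42,P01857,Ig gamma-1 chain C region,57.90,GPSVFPLAPSSK,192,225,453,169
1316,618.9,51.4,2,0.46,P14923,Junction plakoglobin,87.37,VSVELTNSLFK,1815,1296,3931,1850
914,576.8,52.3,2,0.42,P05164,Myeloperoxidase,56.64,IANVFTNAFR,925,727,2198,1956
20233,576.8,52.7,2,0.48,P05164,Myeloperoxidase,56.77,IANVFTNAFR,659,404,1365,778
2998,688.9,46.5,2,0.47,Q13835,Plakophilin-1,66.93,VMGNQVFPEVTR,1035,781,2190,1187
10288,594.3,37.7,2,0.42,Q13835,Plakophilin-1,85.89,LLQSGNSDVVR,413,235,987,597
26579,450.7,36.8,2,0.49,Q13835,Plakophilin-1,50.69,LDAEVPTR,261,181,538,346
1257,582.0,46.1,3,0.48,P06702,Protein S100-A9,65.32,VIEHIMEDLDTNADK,1365,945,2817,1354
2735,807.9,66.0,2,0.48,P06702,Protein S100-A9,111.26,QLSFEEFIMLMAR,829,807,1743,1423
9832,744.3,42.5,2,0.49,P68363,Tubulin alpha-1B chain,87.43,LISQIVSSITASLR,426,143,870,572
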
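case_id,ln_duration_months,systolic_bp,diastolic_bp,nephrotic,sledai,hemoglobin,urine_protein,serum_creatinine,egfr,serum_albumin,anti_dsdna,anti_sm,anti_ro52,anti_ssa,anti_ssb,anti_rnp,anti_cardiolipin,c3,c4,esr
1,36,130,80,1,12,78,6.79,62,98,16,1,0,0,1,0,1,0,59.2,16.2,46
2,180,130,80,0,23,103,0.34,43,113,34,0,1,1,0,0,1,0,72.3,15.7,29
3,48,130,80,0,18,116,1.46,59,105,33,1,0,1,1,0,0,0,51.6,11.6,35
4,84,160,110,1,33,100,4.76,93,62,30,1,0,0,0,0,0,0,49.2,11.1,35
5,156,140,90,1,25,131,7.14,32,108,16,1,0,0,1,0,1,0,55.83,7.82,39
6,24,110,70,1,19,138,6.51,27,124,26,1,0,1,1,0,0,0,53.7,5.06,45
7,24,120,80,0,14,105,1.15,56,113,36,1,0,1,0,1,0,0,67.4,13.4,37
8,2,140,80,0,26,81,2.08,73,80,21,1,1,0,0,0,1,0,35.8,1.76,53
9,2,100,50,0,17,98,0.81,47,120,29,1,1,0,0,1,0,0,33.1,2.67,52
10,33,150,80,1,12,133,4.67,37,113,26,0,0,1,1,1,1,0,57.7,14.2,44
11,0.25,120,80,0,27,92,1.87,136,39,28,1,1,1,1,1,1,1,26.3,3.3,40
12,1,120,80,1,21,108,4.63,56,131,12,1,0,1,1,0,1,0,28.5,3.76,48
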
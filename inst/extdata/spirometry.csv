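subject_id,group,sex,age_yr,height_cm,weight_kg,bmi,FEV1_L,FEV1_pct_pred,FVC_L,FEV1_FVC_pct,FEV1_FVC_pct_pred,PC20_mg_ml
H1,healthy,F,23,153,44,18.8,2.98,100,3.41,87.4,101,NA
H2,healthy,F,22,175,68,22.2,3.67,109,3.88,94.6,108,NA
H3,healthy,M,23,180,82,25.2,4.18,88,4.35,96.1,115,NA
H4,healthy,M,21,189,73,20.4,4.02,79,4.11,97.8,116,NA
A1,asthmatic,F,19,155,54,22.3,2.81,87,3.36,83.6,93,0.12
A2,asthmatic,F,23,157,61,24.7,2.81,91,3.21,87.5,101,0.17
A3,asthmatic,F,21,163,73,27.5,3.35,102,3.73,89.8,104,1.11
A4,asthmatic,M,23,188,93,26.4,4.43,86,5.63,78.7,94,0.17
A5,asthmatic,F,22,172,80,26.9,3.45,94,4.32,79.9,92,3.31
A6,asthmatic,F,22,157,55,22.1,2.51,80,3.34,75.1,87,0.12
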
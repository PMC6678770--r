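case_study,column_name,gradient_time_min,temperature_C,model,pct_rmse_tr,pct_rmse_order
I,Supelcosil LC-18,10,35,MLR,8.57,59.07
I,Supelcosil LC-18,10,35,MLR-NLP,8.07,51.77
II,Xterra MS C18,20,40,MLR,11.50,25.01
II,Xterra MS C18,20,40,MLR-NLP,15.17,22.40
II,LiChrospher RP-18,20,40,MLR,13.25,30.28
II,LiChrospher RP-18,20,40,MLR-NLP,12.42,39.59
II,LiChrospher RP-18,60,40,MLR,25.60,34.11
II,LiChrospher RP-18,60,40,MLR-NLP,37.94,30.10
II,LiChrospher RP-18,120,40,MLR,42.31,153.00
II,LiChrospher RP-18,120,40,MLR-NLP,85.62,25.17
II,LiChrospher RP-18,20,60,MLR,18.45,36.12
II,LiChrospher RP-18,20,60,MLR-NLP,16.86,40.70
II,LiChrospher RP-18,20,80,MLR,18.82,35.25
II,LiChrospher RP-18,20,80,MLR-NLP,21.06,34.65
II,LiChrospher CN,20,40,MLR,39.28,195.82
II,LiChrospher CN,20,40,MLR-NLP,55.53,53.45
II,PLRP-S,20,40,MLR,20.07,69.44
II,PLRP-S,20,40,MLR-NLP,20.72,58.09
II,PLRP-S,60,40,MLR,37.92,107.94
II,PLRP-S,60,40,MLR-NLP,52.40,41.33
II,PLRP-S,20,60,MLR,21.75,94.97
II,PLRP-S,20,60,MLR-NLP,24.06,82.54
II,PLRP-S,60,60,MLR,40.11,321.65
II,PLRP-S,60,60,MLR-NLP,54.35,37.16
II,PLRP-S,20,80,MLR,22.36,137.16
II,PLRP-S,20,80,MLR-NLP,26.19,53.30
II,PLRP-S,60,80,MLR,42.60,194.56
II,PLRP-S,60,80,MLR-NLP,61.56,40.18
II,Discovery RP Amide C16,20,40,MLR,36.73,261.22
II,Discovery RP Amide C16,20,40,MLR-NLP,58.07,91.81
II,Discovery RP Amide C16,20,60,MLR,36.37,219.01
II,Discovery RP Amide C16,20,60,MLR-NLP,57.16,96.70
II,Discovery RP Amide C16,20,80,MLR,36.74,241.63
II,Discovery RP Amide C16,20,80,MLR-NLP,54.75,81.05
II,Discovery HS F5-3,20,40,MLR,12.81,34.00
II,Discovery HS F5-3,20,40,MLR-NLP,13.84,28.12
II,Chromolith,20,40,MLR,20.82,43.81
II,Chromolith,20,40,MLR-NLP,24.36,28.55
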
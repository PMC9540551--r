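condition,outcome,type,es_mean,es_sd,nes_mean,nes_sd,reported_diff
appendicitis,daoh_90,continuous,84.78,6.07,82.50,11.41,2.28
appendicitis,mortality_90,binary_pct,0.19,NA,1.09,NA,-0.90
appendicitis,los_90,continuous,5.09,4.92,6.68,7.59,-1.60
appendicitis,readmit_30,binary_pct,9.06,NA,11.09,NA,-2.03
gallstone_disease,daoh_90,continuous,81.28,10.45,80.74,13.14,0.54
gallstone_disease,mortality_90,binary_pct,0.73,NA,1.50,NA,-0.77
gallstone_disease,los_90,continuous,8.23,8.04,8.22,8.89,0.01
gallstone_disease,readmit_30,binary_pct,10.63,NA,14.43,NA,-3.80
diverticular_disease,daoh_90,continuous,60.92,26.23,79.94,16.71,-19.0
diverticular_disease,mortality_90,binary_pct,9.30,NA,3.04,NA,6.27
diverticular_disease,los_90,continuous,22.38,18.37,7.84,9.42,14.60
diverticular_disease,readmit_30,binary_pct,8.84,NA,9.72,NA,-0.88
hernia,daoh_90,continuous,80.98,16.57,81.63,18.29,-0.65
hernia,mortality_90,binary_pct,2.68,NA,3.69,NA,-1.01
hernia,los_90,continuous,7.08,10.19,5.49,9.32,1.59
hernia,readmit_30,binary_pct,9.43,NA,12.40,NA,-2.97
intestinal_obstruction,daoh_90,continuous,66.56,24.25,68.01,29.74,-1.46
intestinal_obstruction,mortality_90,binary_pct,7.59,NA,13.37,NA,-5.78
intestinal_obstruction,los_90,continuous,18.13,15.68,11.80,13.97,6.33
intestinal_obstruction,readmit_30,binary_pct,9.50,NA,14.72,NA,-5.22
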
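metric,group_a,mean_a,sd_a,n_a,group_b,mean_b,sd_b,n_b
density,TD,9.63,3.23,18,ASD,5.96,2.73,18
mean_ms,TD,90.0,61.6,18,ASD,84.4,187.2,18
sd_ms,TD,311.1,51.8,18,ASD,384.4,86.1,18
kurtosis,TD,0.81,0.84,18,ASD,0.13,1.01,18
speaker_aq,TD,16.56,6.17,18,ASD,15.94,8.36,18
listener_aq,TD,15.56,6.21,18,ASD,30.56,7.47,18
speaker_nod_density,TD,23.30,4.83,18,ASD,24.27,5.17,18
likert_concentration,TD,3.28,1.32,18,ASD,3.44,1.29,18
likert_comprehension,TD,3.44,1.15,18,ASD,3.94,1.16,18
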
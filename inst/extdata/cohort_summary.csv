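interval_months,method,measure,control_mean,control_sd,control_n,patient_mean,patient_sd,patient_n,printed_n_noaging,printed_n_aging
6,seg_subtract_all,gm,0.86,4.24,19,2.20,2.66,37,771,2081
6,seg_subtract_excl,gm,-0.01,1.97,18,2.31,2.60,36,666,661
6,jacobian,gm,0.42,0.47,19,1.77,1.37,37,314,540
6,bbsi,brain,0.51,0.57,19,1.67,1.26,37,296,617
6,siena,brain,0.34,0.89,19,2.03,1.63,37,337,485
12,seg_subtract_all,gm,0.92,2.21,19,2.37,2.86,37,763,2047
12,seg_subtract_excl,gm,0.49,1.19,18,2.76,1.64,36,184,273
12,jacobian,gm,0.46,0.27,19,2.01,0.96,37,120,202
12,bbsi,brain,0.64,0.44,19,1.99,0.91,37,110,240
12,siena,brain,0.67,0.82,19,2.72,1.25,37,111,196
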
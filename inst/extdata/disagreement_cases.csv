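patient_id,br,dpsma_tv,delta_psa_pct,delta_psma_tv_pct,os_days,death
4,PD,PR,238,-76,216,TRUE
8,PD,SD,786,-21,235,TRUE
10,SD,PD,9,42,1169,FALSE
15,PR,PD,-99,213,720,FALSE
18,PD,SD,291,-14,328,TRUE
21,PD,SD,66,26,1556,FALSE
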
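patient_id,percist,new_lesion,br,psa_negative,dpsma_tv_a,dtl_psma_a,dpsma_tv_b,dtl_psma_b
1,SD,FALSE,SD,FALSE,PR,PR,PR,PR
2,PD,TRUE,,TRUE,PD,PD,PD,PD
3,PR,FALSE,PR,FALSE,PR,PR,PR,PR
4,PD,TRUE,PD,FALSE,PR,PR,PR,PR
5,PR,FALSE,PR,FALSE,PR,PR,PR,PR
6,PD,TRUE,PD,FALSE,PD,PD,PD,PD
7,PR,FALSE,PR,FALSE,PR,PR,PR,PR
8,PD,TRUE,PD,FALSE,SD,SD,SD,SD
9,PD,FALSE,SD,FALSE,SD,SD,SD,SD
10,PD,FALSE,SD,FALSE,PD,PD,PD,PD
11,PD,FALSE,PD,FALSE,PD,PD,PD,PD
12,PD,TRUE,PD,FALSE,PD,PD,PD,PD
13,PD,TRUE,PD,FALSE,PD,PD,PD,PD
14,PD,TRUE,PD,FALSE,,,,
15,PD,FALSE,PR,FALSE,PD,PD,PD,PD
16,PD,TRUE,PR,FALSE,PR,PR,PR,PR
17,PD,TRUE,,TRUE,PR,PR,PR,PR
18,PR,FALSE,PD,FALSE,SD,SD,SD,SD
19,PD,TRUE,PD,FALSE,PD,PD,PD,PD
20,PD,FALSE,PD,FALSE,PD,PD,PD,PD
21,PD,TRUE,PD,FALSE,SD,SD,SD,SD
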
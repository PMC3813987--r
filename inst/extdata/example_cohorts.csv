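patient_id,cohort,renal,neurological,hematological
1,1,2,2,2
2,1,1,1,3
3,1,0,0,0
4,2,3,0,0
5,2,0,2,1
6,2,1,0,2
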
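quantity,age_lo,age_hi,mean,ci_lo,ci_hi,units,source
total_cd4_blood,0,0.25,2215.23,2023.43,2407.03,cells_per_uL,meta-analytic weighted average (observed)
memory_cd4_blood,0,0.25,393.33,316.85,469.82,cells_per_uL,meta-analytic weighted average (observed)
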
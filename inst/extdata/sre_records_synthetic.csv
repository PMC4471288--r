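drug,population,t_half_h,rr_sre,citation
fluoxetine,adult,96,0.92,"synthetic illustrative value"
citalopram,adult,35,1.4,"synthetic illustrative value"
sertraline,adult,26,1.5,"synthetic illustrative value"
paroxetine,adult,21,2.1,"synthetic illustrative value"
venlafaxine,adult,5,2.6,"synthetic illustrative value"
fluvoxamine,adult,15,1.9,"synthetic illustrative value"
fluoxetine,pediatric,96,0.92,"synthetic illustrative value"
citalopram,pediatric,38,1.4,"synthetic illustrative value"
sertraline,pediatric,27,1.5,"synthetic illustrative value"
paroxetine,pediatric,11,2.1,"synthetic illustrative value"
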
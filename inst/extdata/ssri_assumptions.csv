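drug,model,volume_l,cmax_ng_ml,tmax_h,t_half_h,ref_dose_mg,km_ng_ml,ka_per_h,vm_ng_ml_h,interval_h,standard_dose_mg,source
fluoxetine,mm,1033,35,7,48,40,448,0.53,6.5,24,40,"single 40-mg dose observables from adult PK literature; fitted constants reported with them"
sertraline,linear,1400,,6.5,26,,,,,24,51,"adult PK summary (V, terminal t1/2, Tmax)"
citalopram,linear,840,,4,35,,,,,24,20.7,"adult PK summary (V, terminal t1/2, Tmax)"
venlafaxine,linear,426,,8,16.9,,,,,24,228.6,"venlafaxine plus O-desmethylvenlafaxine treated as one combined moiety"
paroxetine,mm,,17.6,6.3,16,30,,,,24,41.4,"single 30-mg dose observables; elimination saturable at therapeutic doses"
fluvoxamine,mm,,30,6,19,50,,,,12,41,"single 50-mg dose observables; elimination saturable at therapeutic doses"
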
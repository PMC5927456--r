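variable,max_mean,min_mean,units
wet_weight_ug,82.2,48.8,ug
length_um,1025,821,um
egg_weight_ug,1.17,0.37,ug
clutch_size,9.3,2.1,eggs per sac
nauplii,8.7,1.7,nauplii per female
rre_pct,7.1,2.6,percent
temperature_c,18.1,14.9,degC
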
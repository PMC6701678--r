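disease,param,value,se,ci_low,ci_high
chd,fatal_fraction,0.25,0.025000000000000001,NA,NA
stroke,fatal_fraction,0.20000000000000001,0.020000000000000004,NA,NA
heart_failure,fatal_fraction,0.14999999999999999,0.014999999999999999,NA,NA
chd,first_year_death,0.10000000000000001,0.010000000000000002,NA,NA
stroke,first_year_death,0.14999999999999999,0.014999999999999999,NA,NA
chd,post_multiplier,2,NA,1.5,2.7000000000000002
stroke,post_multiplier,2,NA,1.5,2.7000000000000002
type2_diabetes,mortality_hr,1.8,NA,1.5,2.2000000000000002
breast_cancer,net_survival_5yr,0.84999999999999998,0.02,NA,NA
colorectal_cancer,net_survival_5yr,0.58999999999999997,0.02,NA,NA
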
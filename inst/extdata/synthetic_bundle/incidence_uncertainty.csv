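disease,se_fraction
chd,0.10000000000000001
stroke,0.10000000000000001
heart_failure,0.10000000000000001
type2_diabetes,0.10000000000000001
breast_cancer,0.10000000000000001
colorectal_cancer,0.10000000000000001
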
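disease,utility,se
chd,0.65000000000000002,0.020299999999999999
stroke,0.52000000000000002,0.019199999999999998
heart_failure,0.48999999999999999,0.019400000000000001
type2_diabetes,0.66000000000000003,0.0054000000000000003
breast_cancer,0.76000000000000001,0.013299999999999999
colorectal_cancer,0.67000000000000004,0.031399999999999997
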
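disease,phase,cost,se
chd,first_year,5562,556
chd,subsequent,214,21
chd,fatal_event,1458,146
stroke,first_year,10062,1006
stroke,subsequent,2705,270
stroke,fatal_event,8805,881
heart_failure,first_year,2402,240
heart_failure,subsequent,815,82
heart_failure,fatal_event,0,0
type2_diabetes,first_year,1257,126
type2_diabetes,subsequent,1257,126
type2_diabetes,fatal_event,0,0
breast_cancer,first_year,12155,1215
breast_cancer,subsequent,0,0
breast_cancer,fatal_event,0,0
colorectal_cancer,first_year,16978,1698
colorectal_cancer,subsequent,0,0
colorectal_cancer,fatal_event,0,0
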
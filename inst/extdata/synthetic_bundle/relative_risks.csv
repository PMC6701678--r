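disease,level,rr,ci_low,ci_high
chd,inactive,1,1,1
chd,low,0.84999999999999998,0.73160177996129916,0.98755910631904054
chd,moderate,0.72999999999999998,0.62831682279029222,0.84813899719164665
chd,high,0.67000000000000004,0.5766743442047888,0.7784289426279497
stroke,inactive,1,1,1
stroke,low,0.88,0.75742301925405087,1.0224141336008892
stroke,moderate,0.78000000000000003,0.67135222161154506,0.90623070932806082
stroke,high,0.72999999999999998,0.62831682279029222,0.84813899719164665
heart_failure,inactive,1,1,1
heart_failure,low,0.83999999999999997,0.72299470019704848,0.97594076389175777
heart_failure,moderate,0.71999999999999997,0.61970974302604165,0.83652065476436377
heart_failure,high,0.65000000000000002,0.55946018467628755,0.75519225777338406
type2_diabetes,inactive,1,1,1
type2_diabetes,low,0.80000000000000004,0.68856638114004631,0.92946739418262647
type2_diabetes,moderate,0.65000000000000002,0.55946018467628755,0.75519225777338406
type2_diabetes,high,0.55000000000000004,0.47338938703378181,0.63900883350055571
breast_cancer,inactive,1,1,1
breast_cancer,low,0.93000000000000005,0.80045841807530382,1.0805058457373033
breast_cancer,moderate,0.88,0.75742301925405087,1.0224141336008892
breast_cancer,high,0.84999999999999998,0.73160177996129916,0.98755910631904054
colorectal_cancer,inactive,1,1,1
colorectal_cancer,low,0.90000000000000002,0.774637178782552,1.0456508184554547
colorectal_cancer,moderate,0.80000000000000004,0.68856638114004631,0.92946739418262647
colorectal_cancer,high,0.76000000000000001,0.65413806208304393,0.88299402447349518
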
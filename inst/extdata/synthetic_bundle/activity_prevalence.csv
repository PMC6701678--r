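sex,age_band,level,share
male,16-23,inactive,0.040000000000000001
male,16-23,low,0.14000000000000001
male,16-23,moderate,0.41999999999999998
male,16-23,high,0.40000000000000002
male,24-44,inactive,0.14999999999999999
male,24-44,low,0.23999999999999999
male,24-44,moderate,0.35999999999999999
male,24-44,high,0.25
male,45-64,inactive,0.25
male,45-64,low,0.29999999999999999
male,45-64,moderate,0.29999999999999999
male,45-64,high,0.14999999999999999
male,65plus,inactive,0.40000000000000002
male,65plus,low,0.29999999999999999
male,65plus,moderate,0.22
male,65plus,high,0.080000000000000002
female,16-23,inactive,0.040000000000000001
female,16-23,low,0.14999999999999999
female,16-23,moderate,0.44
female,16-23,high,0.37
female,24-44,inactive,0.17999999999999999
female,24-44,low,0.26000000000000001
female,24-44,moderate,0.34999999999999998
female,24-44,high,0.20999999999999999
female,45-64,inactive,0.28000000000000003
female,45-64,low,0.31
female,45-64,moderate,0.28000000000000003
female,45-64,high,0.13
female,65plus,inactive,0.44
female,65plus,low,0.29999999999999999
female,65plus,moderate,0.19
female,65plus,high,0.070000000000000007
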
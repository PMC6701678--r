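age_group,level,utility,se
16-34,inactive,0.89700000000000002,0.02
16-34,low,0.91800000000000004,0.02
16-34,moderate,0.93700000000000006,0.02
16-34,high,0.94299999999999995,0.02
35-44,inactive,0.77000000000000002,0.02
35-44,low,0.88900000000000001,0.02
35-44,moderate,0.91400000000000003,0.02
35-44,high,0.92700000000000005,0.02
45-54,inactive,0.69599999999999995,0.02
45-54,low,0.85199999999999998,0.02
45-54,moderate,0.89900000000000002,0.02
45-54,high,0.92100000000000004,0.02
55-64,inactive,0.64800000000000002,0.02
55-64,low,0.86099999999999999,0.02
55-64,moderate,0.86299999999999999,0.02
55-64,high,0.90700000000000003,0.02
65-74,inactive,0.65700000000000003,0.02
65-74,low,0.82299999999999995,0.02
65-74,moderate,0.87,0.02
65-74,high,0.89700000000000002,0.02
75plus,inactive,0.70099999999999996,0.02
75plus,low,0.82899999999999996,0.02
75plus,moderate,0.84999999999999998,0.02
75plus,high,0.876,0.02
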
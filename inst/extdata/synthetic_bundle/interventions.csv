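name,delta_mvpa_daily,ci_low,ci_high,cost_per_participant,decay_rate,sustain_years
after_school,4.8399999999999999,-0.93999999999999995,10.609999999999999,51,0.5,1
multicomponent,7,2.7000000000000002,11.4,190,0.5,1
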
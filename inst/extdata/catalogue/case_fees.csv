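cohort,centre_class,configured_fee_eur
HAP,AMC,12871.70
POP,AMC,3400.76
SUEP,AMC,2904.67
SUEP,non-AMC,1071.23
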
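role,rate_eur_per_min,tariff_percent_per_min
SP,0.5498,NA
PH,0.8027,NA
MS,1.2053,NA
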
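gm_prefix	interpretation
S0670	loc_unspecified
S0671	loc_lt30min
S0672	loc_30min_24h
S0673	loc_gt24h_return
S0674	loc_gt24h_no_return
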
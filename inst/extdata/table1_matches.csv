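instance,match_pct
All physicians vs. DSS,19.2
Physician 1 vs. DSS,57.6
Physician 2 vs. DSS,42.3
Physician 3 vs. DSS,46.1
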
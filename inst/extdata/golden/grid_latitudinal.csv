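lat_bin,n_eddies,n_significant,pct_significant
-36,1,0,0
-33,2,0,0
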
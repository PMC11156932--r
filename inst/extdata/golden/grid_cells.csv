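lon_bin,lat_bin,n_eddies,n_significant,pct_significant
-33,-33,1,0,0
-27,-36,1,0,0
-24,-33,1,0,0
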
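characteristic,group,n,q25,median,q75,whisker_low,whisker_high
amplitude_m,null,3,0.1798428917,0.2370337078,0.2441124738,0.08343851848,0.3405168471
trapping,null,3,11.66856534,13.96087287,17.07995047,3.55148765,25.19702816
effective_area_km2,null,3,9817.098224,10313.48402,12516.14242,5768.531929,16564.70871
sst_anomaly,null,3,0.001150245652,0.001813230888,0.009504780868,-0.01138155717,0.02203658369
chl_anomaly,null,3,-0.08797054331,0.02297622786,0.0529940017,-0.2994173608,0.2644408192
age_days,null,3,12.5,13,13.5,11,15
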
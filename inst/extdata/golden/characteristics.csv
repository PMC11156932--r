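eddy_id,amplitude_m,trapping,effective_area_km2,age_days,sst_anomaly,chl_anomaly
1,0.2511912399,20.19902808,9320.712427,14,0.001813230888,0.02297622786
2,0.1226520756,9.376257819,10313.48402,12,0.0004872604162,0.08301177554
3,0.2370337078,13.96087287,14718.80082,13,0.01719633085,-0.1989173145
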
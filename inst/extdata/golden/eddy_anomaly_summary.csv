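eddy_id,polarity,nasc_epipelagic_anomaly,nasc_mesopelagic_anomaly,sst_anomaly,sst_anomaly_degC,chl_anomaly,periods_used
1,CE,-0.1426645548,-0.1426640953,0.001813230888,0.035805,0.02297622786,day
2,CE,-0.09571075432,-0.09570993318,0.0004872604162,0.009633333333,0.08301177554,day+night
3,AE,0.1881390775,0.1881390953,0.01719633085,0.3485366667,-0.1989173145,day+night
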
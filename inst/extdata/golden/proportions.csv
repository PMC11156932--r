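polarity,variable,n,pct_increase,pct_decrease,pct_null,mean_anomaly_increase,mean_anomaly_decrease,mean_anomaly_null
AE,chl,1,0,0,100,,,-0.1989173145
AE,nasc_epipelagic,1,0,0,100,,,0.1881390775
AE,nasc_mesopelagic,1,0,0,100,,,0.1881390953
AE,sst,1,100,0,0,0.01719633085,,
CE,chl,2,0,0,100,,,0.0529940017
CE,nasc_epipelagic,2,0,0,100,,,-0.1191876546
CE,nasc_mesopelagic,2,0,0,100,,,-0.1191870142
CE,sst,2,0,0,100,,,0.001150245652
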
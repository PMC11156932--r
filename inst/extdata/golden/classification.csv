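eddy_id,polarity,variable,outcome,p_value,statistic,n_inside,n_outside
1,CE,nasc_epipelagic,null,0.4,-3,4,3
1,CE,nasc_mesopelagic,null,0.4,-3,4,3
1,CE,sst,null,1,0,4,5
1,CE,chl,null,1,0,4,5
2,CE,nasc_epipelagic,null,0.7150006547,-0.1333333333,3,6
2,CE,nasc_mesopelagic,null,0.7150006547,-0.1333333333,3,6
2,CE,sst,null,0.9047619048,1,3,6
2,CE,chl,null,0.9047619048,1,3,6
3,AE,nasc_epipelagic,null,0.1885934422,0.55,5,6
3,AE,nasc_mesopelagic,null,0.1885934422,0.55,5,6
3,AE,sst,increase,0.004329004329,15,5,6
3,AE,chl,null,0.08225108225,-10,5,6
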
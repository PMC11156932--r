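eddy_id,n_inside,n_control,n_zones,n_inside_day,n_inside_night,n_control_day,n_control_night,retained,drop_reason
1,4,5,4,4,0,3,2,TRUE,
2,3,6,2,1,2,3,3,TRUE,
3,5,6,3,1,4,3,3,TRUE,
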
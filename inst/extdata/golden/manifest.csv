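stage,count
atlas_records,21
atlas_records_lifespan_ok,21
eddies,3
eddies_lifespan_ok,3
profiles,75
profiles_prepared,67
profiles_inside,12
profiles_control,17
eddies_sampled,3
eddies_retained,3
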
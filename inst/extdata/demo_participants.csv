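participant_id,group,years_training,weekly_hours
P01,tori,17.2,14.2
P02,tori,12.7,1.9
P03,tori,9.1,0
P04,tori,6.1,12.8
P05,tori,14.4,14.8
P06,tori,1.7,0
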
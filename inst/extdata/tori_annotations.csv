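region_id,level,t_start_s,t_end_s,label,recording_id,total_duration_s
r01,2,10.1496292091906,12.1585320798215,L2,tori,319.09315514504
r02,2,23.6849781130906,30.5789219457656,L2,tori,319.09315514504
r03,2,41.2851271480322,45.5339205763303,L2,tori,319.09315514504
r04,2,58.0506379208528,62.3377332184464,L2,tori,319.09315514504
r05,1,74.8180927857757,82.5676462875679,L1,tori,319.09315514504
r06,2,93.4471335059032,97.1451245279983,L2,tori,319.09315514504
r07,1,111.092401675321,120.053879527934,L1,tori,319.09315514504
r08,2,132.799803870358,135.959592997516,L2,tori,319.09315514504
r09,2,147.683620221401,149.970301574282,L2,tori,319.09315514504
r10,2,156.122951083072,162.955221906118,L2,tori,319.09315514504
r11,2,171.395863916539,177.463009211281,L2,tori,319.09315514504
r12,1,190.526593086356,196.1367174068,L1,tori,319.09315514504
r13,2,209.667491936823,211.995238090353,L2,tori,319.09315514504
r14,1,219.870582169341,223.450158769172,L1,tori,319.09315514504
r15,2,236.94348539589,242.514266329026,L2,tori,319.09315514504
r16,1,253.047882143548,259.557681819052,L1,tori,319.09315514504
r17,2,272.300005044416,276.643563764123,L2,tori,319.09315514504
r18,2,289.213973201765,295.34641606654,L2,tori,319.09315514504
r19,1,303.586198900966,312.714746046206,L1,tori,319.09315514504
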
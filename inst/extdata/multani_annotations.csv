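region_id,level,t_start_s,t_end_s,label,recording_id,total_duration_s
r01,2,6.31858461850788,10.0539953908417,L2,multani,307.479690668336
r02,2,12.6078803832177,16.1522929027211,L2,multani,307.479690668336
r03,2,22.8357723265886,24.2760530092986,L2,multani,307.479690668336
r04,2,31.5522682853974,33.3982352994382,L2,multani,307.479690668336
r05,2,38.8456203350099,40.949863267364,L2,multani,307.479690668336
r06,2,46.5598253060598,48.4785284226062,L2,multani,307.479690668336
r07,1,54.0308539511869,60.3576352085452,L1,multani,307.479690668336
r08,1,66.1253151394427,73.2606590315467,L1,multani,307.479690668336
r09,2,79.4958009344758,83.3323410066543,L2,multani,307.479690668336
r10,2,89.460172388982,93.1187290521338,L2,multani,307.479690668336
r11,2,98.1337369378889,101.032088961522,L2,multani,307.479690668336
r12,2,107.919265023153,111.427745869756,L2,multani,307.479690668336
r13,2,118.582084345072,122.322717794427,L2,multani,307.479690668336
r14,1,128.244021729543,133.714605911565,L1,multani,307.479690668336
r15,2,140.729669107054,145.044514930574,L2,multani,307.479690668336
r16,2,148.844667748315,152.157565104263,L2,multani,307.479690668336
r17,1,157.591253885604,160.544087649928,L1,multani,307.479690668336
r18,2,167.538373067649,169.304334610445,L2,multani,307.479690668336
r19,2,171.994474272453,176.682670722529,L2,multani,307.479690668336
r20,2,181.369673632598,184.562536318786,L2,multani,307.479690668336
r21,2,189.977348631132,191.736486057472,L2,multani,307.479690668336
r22,2,195.786173727666,199.25496655216,L2,multani,307.479690668336
r23,1,204.009116484691,210.686843495793,L1,multani,307.479690668336
r24,2,213.912891578488,215.418609308708,L2,multani,307.479690668336
r25,2,221.165017587529,223.3534947437,L2,multani,307.479690668336
r26,2,228.16129851318,230.099795730156,L2,multani,307.479690668336
r27,2,233.50251840807,235.449743681029,L2,multani,307.479690668336
r28,2,238.525245297374,242.732534847199,L2,multani,307.479690668336
r29,2,247.066425411822,251.471684664535,L2,multani,307.479690668336
r30,2,256.627470221301,259.543433357147,L2,multani,307.479690668336
r31,1,266.540656720521,272.325799538125,L1,multani,307.479690668336
r32,2,279.897597714048,284.614636560343,L2,multani,307.479690668336
r33,2,290.380636318727,295.135638416372,L2,multani,307.479690668336
r34,1,298.521821829351,303.62290155543,L1,multani,307.479690668336
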
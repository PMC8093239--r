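participant_id,k10_total,psqi_total,scs_total,pa_score,eat_score,mcqa_total,maas_total,bis_total,qol_physical,qol_social,qol_psych,cyberstrife
P001,19,1,72,19,24,43,70,18,55,70,85,FALSE
P002,15,4,57,16,37,74,56,14,90,50,65,FALSE
P003,12,2,83,12,29,56,80,9,70,85,100,FALSE
P004,18,8,68,18,42,39,66,30,50,65,80,TRUE
P005,14,4,53,15,35,70,52,12,85,100,60,FALSE
P006,11,2,79,21,28,52,77,8,65,80,95,FALSE
P007,17,0,64,17,40,34,63,16,100,60,75,FALSE
P008,14,4,90,14,33,65,49,11,80,95,55,FALSE
P009,10,2,75,20,26,48,74,19,60,75,90,FALSE
P010,16,5,60,16,38,30,60,15,95,55,70,FALSE
P011,13,3,86,13,31,61,84,10,75,90,50,TRUE
P012,24,9,72,19,24,43,70,31,55,70,85,TRUE
P013,15,4,57,16,37,74,56,14,90,50,65,FALSE
P014,12,2,83,12,29,56,80,9,70,85,100,FALSE
P015,24,8,30,9,42,84,31,30,50,65,29.4,TRUE
P016,14,18,53,15,35,70,52,25,85,100,60,TRUE
P017,11,2,79,21,28,52,77,8,65,80,95,FALSE
P018,17,0,64,17,40,34,63,16,100,60,75,FALSE
P019,22,16,90,14,33,65,49,24,80,95,55,TRUE
P020,10,2,75,20,26,48,74,19,60,75,90,FALSE
P021,16,5,60,16,38,30,60,15,95,55,70,FALSE
P022,13,3,86,13,31,61,84,10,75,90,50,FALSE
P023,19,1,72,19,24,43,70,18,55,70,85,TRUE
P024,22,20,57,16,37,74,56,26,90,50,65,TRUE
P025,12,2,83,12,29,56,80,9,70,85,100,FALSE
P026,18,0,68,18,42,39,66,17,50,65,80,FALSE
P027,14,4,53,15,35,70,52,12,85,100,60,FALSE
P028,11,2,79,21,28,52,77,8,65,80,95,FALSE
P029,17,6,64,17,40,34,63,28,100,60,75,TRUE
P030,38,16,52,5,14,111,14,24,29.4,44.1,4.9,TRUE
P031,10,2,75,20,26,48,74,19,60,75,90,FALSE
P032,16,5,60,16,38,30,60,15,95,55,70,FALSE
P033,13,3,86,13,31,61,84,10,75,90,50,FALSE
P034,19,1,72,19,24,43,70,18,55,70,85,FALSE
P035,15,20,57,16,37,74,56,26,90,50,65,TRUE
P036,12,2,83,12,29,56,80,9,70,85,100,FALSE
P037,18,0,68,18,42,39,66,17,50,65,80,FALSE
P038,14,4,53,15,35,70,52,12,85,100,60,FALSE
P039,11,12,79,21,28,52,77,20,65,80,95,TRUE
P040,23,6,64,8,40,34,63,28,100,60,75,TRUE
P041,14,16,90,14,33,65,49,24,80,95,55,TRUE
P042,10,2,75,20,26,48,74,19,60,75,90,FALSE
P043,16,5,60,16,38,30,60,15,95,55,70,FALSE
P044,13,3,86,13,31,61,84,10,75,90,50,FALSE
P045,19,1,72,19,24,43,70,18,55,70,85,FALSE
P046,15,20,57,16,37,74,56,26,90,50,65,TRUE
P047,12,2,83,12,29,56,80,9,70,85,100,FALSE
P048,18,0,68,18,42,39,66,17,50,65,80,TRUE
P049,14,18,53,15,35,70,52,25,85,100,60,TRUE
P050,11,2,79,21,28,52,77,8,65,80,95,FALSE
P051,28,6,26,8,21,80,28,28,100,60,24.5,TRUE
P052,14,16,90,14,33,65,49,24,80,95,55,TRUE
P053,25,10,37,10,26,93,38,32,60,75,39.2,TRUE
P054,16,5,60,16,38,30,60,15,95,55,70,FALSE
P055,13,3,86,13,31,61,84,10,75,90,50,FALSE
P056,19,1,72,19,24,43,70,18,55,70,85,FALSE
P057,22,20,19,6,37,120,21,26,90,50,14.7,TRUE
P058,12,2,83,12,29,56,80,9,70,85,100,FALSE
P059,18,0,68,18,42,39,66,17,50,65,80,FALSE
P060,22,18,15,5,35,70,52,25,85,100,9.8,TRUE
P061,11,2,79,21,28,52,77,8,65,80,95,FALSE
P062,17,0,64,17,40,34,63,16,100,60,75,FALSE
P063,14,4,90,14,33,65,49,11,80,95,55,FALSE
P064,10,2,75,20,26,48,74,19,60,75,90,FALSE
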
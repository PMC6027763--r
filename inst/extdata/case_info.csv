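case_id,age,sex,braak_group,braak_stage,pmd_hours,fixation_weeks,clinical_note
1,68,M,control,0,54,7,Cognitively normal
2,55,M,control,0,41,11,Cognitively normal
3,70,M,control,0,72,6,Cognitively normal
4,78,F,control,0,34,8,Cognitively normal
5,73,M,control,0,25,9,Cognitively normal
6,96,F,I_II,2,114,49,Mild dementia
7,77,M,I_II,2,83,15,Cognitively normal
8,94,F,I_II,2,15,9,Cognitively normal
9,70,M,I_II,2,39,7,Multiple psychiatric and physical problems
10,74,F,I_II,1,49,10,Cognitively normal
11,75,M,III_IV,4,82,23,Cognitively normal
12,79,M,III_IV,3,13,15,Cognitively normal
13,81,M,III_IV,3,82,8,Unspecified dementia
14,98,F,III_IV,3,59,8,Cognitively normal
15,91,M,III_IV,3,48,9,Moderate cognitive impairment and vascular disease
16,84,F,V_VI,6,47,16,"Severe dementia, anxiety and depression"
17,77,F,V_VI,6,63,5,Dementia
18,80,F,V_VI,6,32,16,Dementia
19,86,F,V_VI,6,5,6,Dementia
20,89,F,V_VI,6,85,8,Dementia
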
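block,row,16all,16E1,17all,17E2,18all,18E3,Total
head_injuries,ASH,15,12,8,6,5,4,28
head_injuries,FR,2,1,3,1,0,0,5
head_injuries,AEH,2,1,0,0,3,3,5
head_injuries,ICH/CC,0,0,1,1,4,2,5
head_injuries,CI/CA,1,0,1,1,0,0,2
head_injuries,O,2,2,1,1,0,0,3
head_injuries,Total,22,16,14,10,12,9,48
ash_causes,OTHG,7,7,3,1,1,1,11
ash_causes,THG,3,2,4,4,2,2,9
ash_causes,THB,3,2,0,0,0,0,3
ash_causes,C,2,1,0,0,0,0,2
ash_causes,R,,,0,0,1,0,1
ash_causes,S,,,0,0,1,1,1
ash_causes,O,,,1,1,0,0,1
ash_causes,Total,15,12,8,6,5,4,28
spine_injuries,VF,1,1,6,6,6,3,13
spine_injuries,DS,1,1,7,5,5,5,13
spine_injuries,FD,2,0,6,6,3,3,11
spine_injuries,CC,0,0,2,1,4,1,6
spine_injuries,S,1,1,3,3,0,0,4
spine_injuries,CSC,3,2,0,0,2,2,5
spine_injuries,O,1,0,1,1,0,0,2
spine_injuries,Total,9,7,25,22,20,14,54
spine_causes,OT,2,1,3,2,2,1,7
spine_causes,T,2,2,10,10,9,7,21
spine_causes,R,2,1,5,4,3,1,10
spine_causes,M,0,0,2,2,3,3,5
spine_causes,C,0,0,2,1,0,0,2
spine_causes,S,1,1,0,0,0,0,1
spine_causes,SC,3,2,3,3,2,2,8
spine_causes,Total,10,6,25,22,19,14,54
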
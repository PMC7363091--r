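age,experience_years,body_system,injury,cause,site,month,outcome
16,1,head,ASH,OT,H-G,,recovered
16,1,head,ASH,OT,H-G,,recovered
16,1,head,ASH,OT,H-G,,recovered
16,1,head,ASH,OT,H-G,,recovered
16,1,head,ASH,OT,H-G,,recovered
16,1,head,ASH,OT,H-G,,recovered
16,1,head,ASH,OT,H-G,,recovered
16,1,head,ASH,T,H-G,,recovered
16,1,head,ASH,T,H-G,,recovered
16,1,head,ASH,T,H-B,,recovered
16,1,head,ASH,T,H-B,,recovered
16,1,head,ASH,C,,,recovered
16,1,head,FR,,,,unknown
16,1,head,AEH,,,,unknown
16,1,head,O,,,,unknown
16,1,head,O,,,,unknown
17,2,head,ASH,OT,H-G,,recovered
17,2,head,ASH,T,H-G,,sequelae
17,2,head,ASH,T,H-G,,sequelae
17,2,head,ASH,T,H-G,,sequelae
17,2,head,ASH,T,H-G,,sequelae
17,2,head,ASH,O,,,sequelae
17,2,head,FR,,,,unknown
17,2,head,ICH/CC,,,,unknown
17,2,head,CI/CA,,,,unknown
17,2,head,O,,,,unknown
18,3,head,ASH,OT,H-G,,sequelae
18,3,head,ASH,T,H-G,,death
18,3,head,ASH,T,H-G,,death
18,3,head,ASH,SV,,,unknown
18,3,head,AEH,,,,unknown
18,3,head,AEH,,,,unknown
18,3,head,AEH,,,,unknown
18,3,head,ICH/CC,,,,unknown
18,3,head,ICH/CC,,,,unknown
16,2,head,ASH,T,H-G,,unknown
16,2,head,ASH,T,H-B,,unknown
16,2,head,ASH,C,,,unknown
16,2,head,FR,,,,unknown
16,2,head,AEH,,,,unknown
16,2,head,CI/CA,,,,unknown
17,3,head,ASH,OT,H-G,,unknown
17,3,head,ASH,OT,H-G,,unknown
17,3,head,FR,,,,unknown
17,3,head,FR,,,,unknown
18,4,head,ASH,R,,,unknown
18,4,head,ICH/CC,,,,unknown
18,4,head,ICH/CC,,,,unknown
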
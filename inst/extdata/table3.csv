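block,row,col,value
sites,T,H-G,12
sites,T,H-H,1
sites,T,H-L,0
sites,T,H-B,0
sites,T,LH,0
sites,T,O,0
sites,T,Total,13
sites,OT,H-G,6
sites,OT,H-H,4
sites,OT,H-L,5
sites,OT,H-B,7
sites,OT,LH,3
sites,OT,O,2
sites,OT,Total,27
sites,R,H-G,0
sites,R,H-H,0
sites,R,H-L,2
sites,R,H-B,0
sites,R,LH,0
sites,R,O,0
sites,R,Total,2
sites,C,H-G,1
sites,C,H-H,2
sites,C,H-L,0
sites,C,H-B,0
sites,C,LH,0
sites,C,O,1
sites,C,Total,4
sites,S,H-G,0
sites,S,H-H,0
sites,S,H-L,1
sites,S,H-B,0
sites,S,LH,0
sites,S,O,0
sites,S,Total,1
sites,O,H-G,0
sites,O,H-H,0
sites,O,H-L,0
sites,O,H-B,0
sites,O,LH,0
sites,O,O,0
sites,O,Total,1
load,T,MW,4
load,T,LH,7
load,T,H-B,4
load,T,N-B,2
load,T,O,4
load,T,Total,21
load,OT,MW,2
load,OT,LH,0
load,OT,H-B,0
load,OT,N-B,3
load,OT,O,2
load,OT,Total,7
load,R,MW,8
load,R,LH,0
load,R,H-B,0
load,R,N-B,0
load,R,O,2
load,R,Total,10
load,C,MW,0
load,C,LH,0
load,C,H-B,2
load,C,N-B,0
load,C,O,0
load,C,Total,2
load,S,MW,0
load,S,LH,0
load,S,H-B,1
load,S,N-B,0
load,S,O,0
load,S,Total,1
load,SC,MW,8
load,SC,LH,0
load,SC,H-B,0
load,SC,N-B,0
load,SC,O,0
load,SC,Total,8
load,M,MW,5
load,M,LH,0
load,M,H-B,0
load,M,N-B,0
load,M,O,0
load,M,Total,5
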
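block,row,col,value
population,count,-12,19975
population,count,-15,10510
population,count,-18,24918
population,count,-22,10693
population,count,23-,26204
population,count,women,570
population,count,Total,93873
population,percent,-12,21
population,percent,-15,11
population,percent,-18,27
population,percent,-22,12
population,percent,23-,28
population,percent,women,1
population,percent,Total,100
serious_injuries,Head,-18,48
serious_injuries,Head,-18_percent,41
serious_injuries,Head,Total,117
serious_injuries,Spine,-18,54
serious_injuries,Spine,-18_percent,41
serious_injuries,Spine,Total,133
serious_injuries,ChestAbdominal,-18,4
serious_injuries,ChestAbdominal,-18_percent,50
serious_injuries,ChestAbdominal,Total,8
serious_injuries,Circulation,-18,10
serious_injuries,Circulation,-18_percent,38
serious_injuries,Circulation,Total,26
months,HI,4,2
months,HI,5,0
months,HI,6,5
months,HI,7,4
months,HI,8,14
months,HI,9,3
months,HI,10,6
months,HI,11,3
months,HI,12,2
months,HI,1,5
months,HI,2,0
months,HI,3,3
months,HI,nc,0
months,ASI,4,6
months,ASI,5,3
months,ASI,6,2
months,ASI,7,4
months,ASI,8,7
months,ASI,9,4
months,ASI,10,7
months,ASI,11,3
months,ASI,12,2
months,ASI,1,5
months,ASI,2,7
months,ASI,3,3
months,ASI,nc,2
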
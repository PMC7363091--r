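block,row,col,value
by_year,Head,2007,2
by_year,Head,2008,0
by_year,Head,2009,0
by_year,Head,2010,0
by_year,Head,2011,1
by_year,Head,2012,3
by_year,Head,2013,1
by_year,Head,2014,0
by_year,Head,2015,1
by_year,Head,2016,0
by_year,Head,2017,1
by_year,Head,2018,1
by_year,Spine,2007,0
by_year,Spine,2008,0
by_year,Spine,2009,1
by_year,Spine,2010,0
by_year,Spine,2011,0
by_year,Spine,2012,2
by_year,Spine,2013,0
by_year,Spine,2014,0
by_year,Spine,2015,1
by_year,Spine,2016,0
by_year,Spine,2017,0
by_year,Spine,2018,1
by_year,ChestAbdominal,2007,0
by_year,ChestAbdominal,2008,0
by_year,ChestAbdominal,2009,0
by_year,ChestAbdominal,2010,0
by_year,ChestAbdominal,2011,0
by_year,ChestAbdominal,2012,0
by_year,ChestAbdominal,2013,0
by_year,ChestAbdominal,2014,0
by_year,ChestAbdominal,2015,0
by_year,ChestAbdominal,2016,0
by_year,ChestAbdominal,2017,2
by_year,ChestAbdominal,2018,0
by_year,Heatstroke,2007,0
by_year,Heatstroke,2008,0
by_year,Heatstroke,2009,1
by_year,Heatstroke,2010,1
by_year,Heatstroke,2011,0
by_year,Heatstroke,2012,0
by_year,Heatstroke,2013,0
by_year,Heatstroke,2014,0
by_year,Heatstroke,2015,0
by_year,Heatstroke,2016,0
by_year,Heatstroke,2017,0
by_year,Heatstroke,2018,0
by_age,Head,13,4
by_age,Head,14,4
by_age,Head,15,3
by_age,Spine,14,4
by_age,Spine,15,1
by_age,ChestAbdominal,-12,1
causes,Head,T,3
causes,Head,OT,5
causes,Head,R,1
causes,Head,O,2
causes,Spine,T,2
causes,Spine,OT,1
causes,Spine,M,2
causes,ChestAbdominal,R,1
causes,ChestAbdominal,M,1
sequelae,ASH,possible_sequelae,2
sequelae,ASH,Total,8
sequelae,ASH,H-G,3
sequelae,ASH,nc,3
sequelae,ICH/CC,possible_sequelae,1
sequelae,ICH/CC,Total,2
sequelae,ICH/CC,H-G,1
sequelae,TSH,Total,1
sequelae,TSH,H-G,1
sequelae,FR,Total,3
sequelae,FR,H-H/B,3
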
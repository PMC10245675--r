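id,route,start,days,sex,length_m,mean_km_day,total_km,sum_steps_km,si,mpm_included
98_20162,offshore,1998-10-05,57,M,4.75,58.1,37.2,619.0,0.060,TRUE
99_20168,offshore,1999-09-17,40,M,4.44,57.5,159.2,345.6,0.461,TRUE
17_172067,offshore,2017-09-20,35,M,4.88,65.3,311.6,767.2,0.406,TRUE
17_172065,offshore,2017-10-06,56,M,4.58,67.4,219.4,795.2,0.276,TRUE
17_172068,offshore,2017-09-23,34,F,3.75,40.4,348.7,567.4,0.615,TRUE
17_172253,offshore,2017-10-07,27,F,3.90,55.6,390.2,787.4,0.496,TRUE
97_6335,nearshore,1997-09-28,41,M,4.40,25.6,394.1,560.8,0.703,TRUE
98_3961,nearshore,1998-09-19,46,M,5.00,51.0,68.5,766.6,0.089,TRUE
98_20696,nearshore,1998-10-04,10,F,3.80,44.2,416.4,597.5,0.697,FALSE
99_3964,nearshore,1999-09-26,66,M,4.10,27.6,465.4,601.1,0.774,TRUE
99_20687,nearshore,1999-10-01,20,F,3.90,30.0,382.9,587.7,0.652,FALSE
99_20689,nearshore,1999-10-03,28,F,4.05,17.4,159.2,319.5,0.498,TRUE
17_172062,nearshore,2017-10-09,53,M,4.66,52.4,491.7,797.8,0.616,TRUE
17_172066,nearshore,2017-09-23,29,M,4.32,65.5,322.5,443.2,0.728,TRUE
17_172070,nearshore,2017-10-07,48,F,4.25,36.7,501.3,654.4,0.766,TRUE
17_148687,nearshore,2017-10-14,17,F,3.70,17.7,389.0,581.6,0.669,FALSE
17_148688,nearshore,2017-10-06,24,M,3.60,32.3,405.7,624.1,0.650,FALSE
17_148690,nearshore,2017-10-23,8,F,3.70,74.1,237.2,466.1,0.509,FALSE
17_148696,nearshore,2017-10-18,13,F,3.80,51.9,534.3,708.5,0.754,FALSE
17_148694,nearshore,2017-10-17,15,F,4.08,49.8,474.6,822.1,0.577,FALSE
18_174728,nearshore,2018-09-27,37,F,3.57,62.9,586.0,901.0,0.650,TRUE
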
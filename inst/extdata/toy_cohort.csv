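sex,age,bmi,date,vitd_nmol_l,supplemented
M,45,24.0,2005-01-01,60,0
F,52,20.0,2005-08-22,69.1,0
M,70,26.0,2005-03-11,35,0
F,40,42.0,2005-06-15,50,0
F,58,23.5,2005-11-30,28,1
M,63,31.2,2005-05-05,41,0
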
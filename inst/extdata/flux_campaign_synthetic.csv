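mast,level,W_m,dh_m,dt_h,area_m2,front_mass_ug,back_mass_ug
1,1,15,1,2,1e-4,86.26422047660544,10
2,1,18,1,2,1e-4,73.55351706383787,10
3,1,20,1,2,1e-4,67.19816535745409,10
1,2,15,1.5,2,1e-4,34.88967537128986,10
2,2,18,1.5,2,1e-4,30.741396142741557,10
3,2,20,1.5,2,1e-4,28.6672565284674,10
1,3,15,2,2,1e-4,16.867299899896544,10
2,3,18,2,2,1e-4,15.722749916580456,10
3,3,20,2,2,1e-4,15.150474924922408,10
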
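strain,mu_aero,mu_anaero,v_glc_aero,v_glc_anaero,v_ac_aero,v_ac_anaero,v_o2_max,gam_aero,gam_anaero,err_mu_aero_pct,err_mu_anaero_pct,err_ac_aero_pct,err_ac_anaero_pct
B21,0.76,0.29,8,11.3,0,9.17,15.5,60.25,50.45,0,0,0,3.9
Crooks,0.96,0.77,12.5,30.9,0,25.2,33.5,121.45,59.75,0,0,0,32
MG1655,0.84,0.46,9.5,16.7,3.49,13.27,13.9,60.25,50.45,15.2,0,0,13.3
W,0.97,0.9,9.9,27.2,0,20.53,17.8,54.55,35.65,0,0,0,2.6
W3110,0.61,0.52,6.7,17.5,3.03,13.63,7.5,36.65,41.65,0,0,2.7,28.7
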
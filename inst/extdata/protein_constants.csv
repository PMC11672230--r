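name,mw_g_mol,volume_A3,sld_h2o_A2,sld_cm4_A2,sld_d2o_A2
COE-3,144827,171740,1.94e-06,2.88e-06,3.36e-06
Fc,49970,59664,1.906e-06,2.79e-06,3.25e-06
Fab,47429,56038,1.95e-06,2.91e-06,3.41e-06
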
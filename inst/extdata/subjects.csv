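subject,age_yrs,mass_kg,height_m,affected_side,k_level
TF01,24,86,1.67,left,K4
TF02,43,66,1.73,left,K4
TF03,71,66,1.65,left,K3-K4
TF04,45,54,1.64,left,K3
TF05,23,75,1.80,left,K4
TF06,40,82,1.82,left,K4
TF07,49,72,1.73,left,K3-K4
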
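subject,none,small,medium,large
TF01,42,44,34,42
TF02,46,51,45,20
TF03,46,44,50,30
TF04,36,38,51,43
TF05,14,48,69,13
TF06,13,73,58,12
TF07,8,63,43,42
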
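segment,mass_fraction,com_fraction,gyration_fraction,length_fraction
head_neck,0.0810,0.500,0.495,0.182
trunk,0.4970,0.500,0.496,0.288
upper_arm_L,0.0280,0.436,0.322,0.186
upper_arm_R,0.0280,0.436,0.322,0.186
forearm_L,0.0160,0.430,0.303,0.146
forearm_R,0.0160,0.430,0.303,0.146
hand_L,0.0060,0.506,0.297,0.108
hand_R,0.0060,0.506,0.297,0.108
thigh_L,0.1000,0.433,0.323,0.245
thigh_R,0.1000,0.433,0.323,0.245
shank_L,0.0465,0.433,0.302,0.246
shank_R,0.0465,0.433,0.302,0.246
foot_L,0.0145,0.500,0.475,0.152
foot_R,0.0145,0.500,0.475,0.152
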
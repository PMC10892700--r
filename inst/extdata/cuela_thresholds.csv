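channel,green_lo,green_hi,yellow_lo,yellow_hi
upper_arm_flexion_left,-20,20,-60,60
upper_arm_flexion_right,-20,20,-60,60
upper_arm_abduction_left,-10,30,-30,60
upper_arm_abduction_right,-10,30,-30,60
lower_arm_flexion_left,60,100,0,140
lower_arm_flexion_right,60,100,0,140
wrist_flexion_left,-15,15,-45,45
wrist_flexion_right,-15,15,-45,45
wrist_deviation_left,-10,10,-20,20
wrist_deviation_right,-10,10,-20,20
wrist_twist_left,-30,30,-60,60
wrist_twist_right,-30,30,-60,60
neck_flexion,0,25,-10,45
trunk_flexion,-5,20,-10,60
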
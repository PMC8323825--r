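beam,wire,membrane,rupture_force_mn,tilt_angle_deg
beam1,50 um W,pia_only,2.96,0.92
beam2,100 um SS,pia_only,19.61,1.25
beam3,50 um W,dura_pia,55.53,1.75
beam4,100 um SS,dura_pia,131.99,1.22
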
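membrane,material,tip,diameter_um,penetrated,total
pia_only,tungsten,sharp,25,10,11
pia_only,tungsten,sharp,50,11,11
pia_only,tungsten,sharp,100,10,10
pia_only,tungsten,blunt,12,8,9
pia_only,tungsten,blunt,25,11,11
pia_only,tungsten,blunt,50,10,10
pia_only,tungsten,blunt,100,11,11
pia_only,stainless_steel,blunt,12,10,11
pia_only,stainless_steel,blunt,25,10,10
pia_only,stainless_steel,blunt,50,11,11
pia_only,stainless_steel,blunt,100,10,10
dura_pia,tungsten,sharp,25,10,14
dura_pia,tungsten,sharp,50,14,14
dura_pia,tungsten,sharp,100,14,14
dura_pia,tungsten,blunt,25,8,14
dura_pia,tungsten,blunt,50,13,14
dura_pia,tungsten,blunt,100,12,12
dura_pia,stainless_steel,blunt,25,6,14
dura_pia,stainless_steel,blunt,50,13,14
dura_pia,stainless_steel,blunt,100,13,13
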
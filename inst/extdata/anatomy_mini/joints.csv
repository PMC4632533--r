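# segbody-anatomy v1
joint,segment,x,y,z
ankle,foot,0.000000000000000000,0.00,0
tibiofemoral,shank,0.000000000000000000,0.00,0
hip,thigh,0.000000000000000000,0.00,0
patellofemoral,patella,-0.029999999999999999,0.01,0
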
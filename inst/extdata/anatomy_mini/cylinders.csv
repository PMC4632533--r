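# segbody-anatomy v1
id,segment,axis_x,axis_y,axis_z,dir_x,dir_y,dir_z,radius,wrap_side
fem_condyle,thigh,0,-0.42499999999999993,0,0,0,1,0.032000000000000001,-1
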
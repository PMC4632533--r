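# segbody-anatomy v1
muscle,order,segment,x,y,z
tibialis_anterior,1,shank,0.035000000000000003,-0.40000000000000002,0
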
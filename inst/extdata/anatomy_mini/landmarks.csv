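# segbody-anatomy v1
name,segment,x,y,z
tibial_tuberosity,shank,0.055,-0.070000000000000007,0
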
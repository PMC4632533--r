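# segbody-anatomy v1
name,upper_bound,origin_segment,origin_x,origin_y,origin_z,insertion_segment,insertion_x,insertion_y,insertion_z
anterior_cruciate,2000,thigh,-0.0050000000000000001,-0.40999999999999998,0.000000000000000000,shank,0.0149999999999999994,-0.025000000000000001,0.000000000000000000
medial_collateral,3000,thigh,0.0000000000000000000,-0.40000000000000002,-0.044999999999999998,shank,0.0050000000000000001,-0.070000000000000007,-0.040000000000000001
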
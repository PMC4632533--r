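# segbody-anatomy v1
name,ref_length,massless
foot,0.174642491965729812,FALSE
shank,0.429999999999999993,FALSE
thigh,0.429999999999999993,FALSE
pelvis,0.239999999999999991,FALSE
patella,0.040000000000000001,TRUE
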
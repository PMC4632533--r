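# segbody-anatomy v1
key,value
schema_version,1
patellar_tendon_length,0.050000000000000003
patellar_tendon_x,0
patellar_tendon_y,0
patellar_tendon_z,0
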
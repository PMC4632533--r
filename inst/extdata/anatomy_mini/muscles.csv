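# segbody-anatomy v1
name,pcsa,group,cylinder,origin_segment,origin_x,origin_y,origin_z,insertion_segment,insertion_x,insertion_y,insertion_z
soleus,0.0057999999999999996,other,,shank,-0.035000000000000003,-0.149999999999999994,0.000000000000000000,foot,-0.0658488084460949058,0.025766925044124100,0.000000000000000000
tibialis_anterior,0.0019000000000000000,other,,shank,0.029999999999999999,-0.200000000000000011,0.000000000000000000,foot,-0.0057259833431386698,-0.111656675191203994,0.000000000000000000
vastus_intermedius,0.0040000000000000001,quadriceps,fem_condyle,thigh,0.020000000000000000,-0.250000000000000000,0.000000000000000000,patella,0.0149999999999999994,0.032000000000000001,0.000000000000000000
rectus_femoris,0.0028000000000000000,quadriceps,fem_condyle,pelvis,-0.014127015068668701,-0.038318384547171798,0.086400000000000005,patella,0.0149999999999999994,0.035999999999999997,0.000000000000000000
hamstring_medialis,0.0023000000000000000,other,,pelvis,-0.097502817255177898,-0.057643901610269901,0.066400000000000001,shank,0.0149999999999999994,-0.070000000000000007,-0.035000000000000003
gluteus,0.0086999999999999994,other,,pelvis,-0.141675427685117011,-0.022305813266318999,0.126400000000000012,thigh,-0.0299999999999999989,-0.130000000000000004,0.055000000000000000
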
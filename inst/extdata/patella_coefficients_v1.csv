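# segbody patella posture coefficients, schema v1 (degrees; theta in degrees)
variable,b0,b1,b2,b3,b4
pt_sagittal,20.4,-0.260,0,0,0
pt_coronal,10.9,-0.233,0.00189,-5.69e-06,0
patellar_flexion,5.59,0.660,0,0,0
patellar_tilt,1.63,0.0667,0.000144,-5.37e-06,0
patellar_rotation,1.43,0.106,-0.00345,5.47e-05,-2.38e-07
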
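metabolite,role,center,offsets,weights,fit_lo,fit_hi,group
TSP,reference,0.000,0,1,-0.05,0.05,
Alanine,panel,1.480,-0.006;0.006,1;1,1.440,1.520,
Lactate,panel,1.330,-0.006;0.006,1;1,1.290,1.370,
Citrate,panel,2.600,-0.075;-0.049;0.049;0.075,1;1;1;1,2.490,2.700,
DMA,panel,2.720,0,1,2.705,2.760,
Creatinine,panel,3.045,0,1,3.000,3.090,
Glucose,panel,5.233,-0.0032;0.0032,1;1,5.190,5.300,gluc
Glucuronate,panel,5.262,-0.0032;0.0032,1;1,5.190,5.300,gluc
Urea,panel,5.780,0,1,5.700,5.860,
PAQ,panel,7.420,0,1,7.380,7.460,
Hippurate,panel,7.830,-0.0065;0.0065,1;1,7.790,7.880,
Trigonelline,panel,9.120,0,1,9.070,9.170,
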
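locus,Fis,Fit,Fst,Nm
p15,-0.227,-0.103,0.136,1.588
p23,0.525,0.699,0.366,0.433
p30,0.026,0.108,0.084,2.737
p31,-0.465,-0.233,0.158,1.331
p33,-0.208,-0.025,0.152,1.397
p40,-0.613,-0.395,0.135,1.604
p46,-0.562,-0.329,0.149,1.429
p49,-1.406,-0.750,0.273,0.666
p53,0.301,0.463,0.232,0.829
p54,0.152,0.468,0.372,0.421
p56,0.524,0.741,0.456,0.298
p69,-0.087,0.254,0.314,0.546
p76,0.610,0.719,0.280,0.641
p79,0.290,0.514,0.315,0.542
p92,-0.039,0.202,0.232,0.828
p95,-0.255,-0.111,0.115,0.922
p111,0.210,0.430,0.278,0.648
p125,0.487,0.658,0.333,0.500
p127,0.394,0.472,0.128,1.696
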
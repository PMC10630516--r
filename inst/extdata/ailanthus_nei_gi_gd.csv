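pop1,pop2,GI,GD
NX,SHX,0.938,0.064
NX,HN,0.893,0.114
NX,TJ,0.669,0.042
NX,BJ,0.850,0.163
NX,HB,0.840,0.175
NX,SHD,0.375,0.982
SHX,HN,0.917,0.086
SHX,TJ,0.660,0.415
SHX,BJ,0.887,0.120
SHX,HB,0.852,0.160
SHX,SHD,0.363,1.012
HN,TJ,0.654,0.425
HN,BJ,0.870,0.139
HN,HB,0.844,0.170
HN,SHD,0.363,1.014
TJ,BJ,0.702,0.354
TJ,HB,0.641,0.445
TJ,SHD,0.250,1.386
BJ,HB,0.853,0.159
BJ,SHD,0.359,1.024
HB,SHD,0.564,0.573
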
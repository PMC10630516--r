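locus,N,Na,Ne,I,Ho,He,uHe,F,PIC
p15,120,12,4.520,1.727,0.800,0.779,0.782,-0.027,0.745
p23,112,16,4.743,2.036,0.259,0.789,0.793,0.672,0.773
p30,120,7,1.550,0.797,0.333,0.355,0.356,0.061,0.340
p31,116,11,4.900,1.889,0.931,0.796,0.799,-0.170,0.771
p33,118,20,11.942,2.675,0.873,0.916,0.920,0.047,0.912
p40,115,7,2.933,1.258,0.852,0.659,0.662,-0.293,0.603
p46,120,12,3.624,1.685,0.892,0.724,0.727,-0.231,0.742
p49,119,16,1.874,1.142,0.857,0.466,0.468,-0.838,0.443
p53,105,15,5.010,2.035,0.429,0.800,0.804,0.465,0.784
p54,107,12,4.328,1.807,0.570,0.769,0.773,0.259,0.744
p56,115,8,2.220,1.130,0.191,0.550,0.552,0.652,0.510
p69,116,10,2.499,1.238,0.345,0.600,0.602,0.425,0.556
p76,95,16,7.462,2.300,0.253,0.866,0.871,0.708,0.854
p79,119,13,4.195,1.748,0.303,0.762,0.765,0.603,0.736
p92,119,14,2.957,1.645,0.361,0.662,0.665,0.454,0.642
p95,119,7,2.350,1.135,0.630,0.575,0.577,-0.097,0.529
p111,114,9,4.039,1.670,0.395,0.752,0.756,0.475,0.724
p125,105,8,3.111,1.401,0.295,0.679,0.682,0.565,0.636
p127,117,8,3.609,1.574,0.231,0.723,0.726,0.681,0.693
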
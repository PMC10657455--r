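# F0: 240
# Fm: 500
"time","phase","F","Fm_prime","I"
30,"D",237.604686863208,499.577248462809,0
60,"D",240.31184465784,497.687948258697,0
90,"D",240.280340399153,500,0
120,"D",242.401185523122,499.149278799421,0
150,"D",234.373267064065,485.169144490453,0
180,"L1",256.329049460071,470.168691123135,22
210,"L1",262.780612353047,475.755216781743,22
240,"L1",260.832726439328,474.082964250584,22
270,"L1",263.445498695532,480.966690062554,22
300,"L1",263.495835007699,481.194726433313,22
330,"L2",202.26863553406,240.838735749612,337
360,"L2",198.880592214142,236.818850881876,337
390,"L2",203.623494832689,241.94828578919,337
420,"L2",196.837362156585,235.260036245447,337
450,"L2",201.65977412603,239.205592506901,337
480,"D2",237.482238681812,500,0
510,"D2",238.272300661635,492.290595946758,0
540,"D2",238.883625096329,500,0
570,"D2",241.811451669529,500,0
600,"D2",238.617731158307,499.675793772217,0
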
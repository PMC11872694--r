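attribute,f_M,f_O,f_A,f_I,f_R,f_Q
A1,153,114,74,95,0,0
A2,118,152,71,95,0,0
A3,105,87,134,110,0,0
B1,142,100,82,112,0,0
B2,96,73,74,193,0,0
C1,131,100,86,119,0,0
C2,132,95,95,114,0,0
C3,78,68,82,208,0,0
C4,63,61,96,216,0,0
C5,78,73,69,216,0,0
D1,157,91,118,70,0,0
D2,179,161,61,35,0,0
D3,166,159,78,33,0,0
D4,123,96,86,131,0,0
D5,135,109,100,92,0,0
E1,95,83,154,104,0,0
E2,87,75,105,169,0,0
E3,154,97,103,82,0,0
E4,107,86,148,95,0,0
F1,70,110,101,155,0,0
F2,83,122,78,153,0,0
F3,101,150,105,80,0,0
F4,113,99,78,146,0,0
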
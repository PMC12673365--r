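pair,syn_overall,nonsyn_overall,best_overall,syn_morphed,nonsyn_morphed,best_morphed
FrHorn->Flute,2.546,3.789,3.879,-0.139,0.906,-1.065
Flute->FrHorn,2.311,3.824,4.001,-0.007,0.738,-0.769
Oboe->Flute,2.388,3.814,4.473,-2.154,1.856,0.370
Flute->Oboe,2.847,3.708,4.366,2.714,-1.339,-0.168
Piano->Flute,4.643,3.846,3.710,4.386,2.931,4.718
Flute->Piano,4.049,3.136,2.913,1.963,-1.092,0.738
Flute->Violin,2.859,4.235,4.316,0.156,0.930,1.006
Violin->Flute,2.776,4.550,4.437,0.559,0.004,1.550
FrHorn->Violin,2.713,3.389,4.787,1.129,-1.446,2.958
Violin->FrHorn,2.814,3.536,5.608,1.496,2.267,6.421
Oboe->Violin,3.115,3.536,3.344,2.572,-0.380,2.202
Violin->Oboe,2.590,3.748,3.944,0.111,1.744,5.409
Piano->Violin,4.311,5.447,1.400,2.414,4.761,-3.308
Violin->Piano,4.772,4.253,2.906,5.991,0.283,6.660
Oboe->FrHorn,1.489,3.563,1.645,-1.062,-0.392,-1.477
FrHorn->Oboe,1.817,4.015,1.925,1.500,0.516,0.722
Piano->FrHorn,4.500,4.339,3.664,2.988,2.125,2.590
FrHorn->Piano,4.727,4.128,3.305,4.984,1.239,1.514
Piano->Oboe,4.889,4.087,2.711,3.649,1.193,-1.954
Oboe->Piano,5.161,4.347,3.110,4.845,1.481,-0.948
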
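pair,syn_overall,nonsyn_overall,best_overall,syn_morphed,nonsyn_morphed,best_morphed
FrHorn->Flute,28.645,39.336,39.922,3.435,9.538,16.883
Flute->FrHorn,25.368,42.476,38.333,2.194,6.131,5.215
Oboe->Flute,30.237,48.325,42.058,8.539,13.730,11.108
Flute->Oboe,32.797,41.357,41.755,13.949,12.747,12.518
Piano->Flute,42.427,42.734,48.168,24.378,20.671,27.810
Flute->Piano,38.120,44.794,26.793,14.194,22.954,9.627
Flute->Violin,32.072,49.821,59.523,7.955,11.824,31.260
Violin->Flute,31.008,45.127,39.267,6.758,9.106,15.832
FrHorn->Violin,26.248,44.552,39.963,6.300,8.887,21.625
Violin->FrHorn,31.860,48.870,56.575,14.410,11.464,46.843
Oboe->Violin,34.972,44.694,39.417,19.549,6.794,19.800
Violin->Oboe,37.136,43.270,59.980,16.379,11.232,51.090
Piano->Violin,36.770,56.225,50.992,15.914,23.346,36.675
Violin->Piano,43.477,49.071,57.915,27.030,10.167,47.730
Oboe->FrHorn,29.483,45.332,33.850,12.796,11.864,19.460
FrHorn->Oboe,22.643,43.867,31.543,11.736,4.455,22.875
Piano->FrHorn,36.802,44.186,54.017,20.715,17.324,45.457
FrHorn->Piano,37.849,43.773,34.935,22.529,9.139,21.995
Piano->Oboe,40.409,45.311,30.678,18.704,8.134,16.580
Oboe->Piano,41.563,47.572,30.082,26.812,8.783,12.548
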
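{
  "flute": {
    "label": "flute",
    "f0": 261.63,
    "partial_amps": [
      1.0,
      0.25,
      0.111111,
      0.0625,
      0.04,
      0.027778,
      0.020408,
      0.015625,
      0.012346,
      0.01,
      0.008264,
      0.006944,
      0.005917,
      0.005102,
      0.004444,
      0.003906,
      0.00346,
      0.003086,
      0.00277,
      0.0025
    ],
    "noise_level": 0.12,
    "noise_tilt_db_oct": -2,
    "attack_level": 0.04,
    "attack_decay_ms": 50,
    "duration": 2,
    "sample_rate": 44100
  },
  "oboe": {
    "label": "oboe",
    "f0": 261.63,
    "partial_amps": [
      1.093265,
      0.630234,
      0.561536,
      0.386329,
      0.191505,
      0.106446,
      0.080201,
      0.066998,
      0.057476,
      0.050119,
      0.044278,
      0.039543,
      0.035635,
      0.032362,
      0.029586,
      0.027205,
      0.025143,
      0.023342,
      0.021758,
      0.020355,
      0.019104,
      0.017983,
      0.016973,
      0.016059,
      0.015229,
      0.014472,
      0.013779,
      0.013143,
      0.012557,
      0.012016
    ],
    "noise_level": 0.012,
    "noise_tilt_db_oct": -3,
    "attack_level": 0.03,
    "attack_decay_ms": 40,
    "duration": 2,
    "sample_rate": 44100
  },
  "horn": {
    "label": "horn",
    "f0": 261.63,
    "partial_amps": [
      1.0,
      0.329877,
      0.172427,
      0.108819,
      0.076146,
      0.05688,
      0.044447,
      0.035897,
      0.029731,
      0.025119,
      0.021566,
      0.018763,
      0.016508,
      0.014662,
      0.01313,
      0.011842,
      0.010747,
      0.009808,
      0.008995,
      0.008286,
      0.007664,
      0.007114,
      0.006626,
      0.00619,
      0.005798
    ],
    "noise_level": 0.008,
    "noise_tilt_db_oct": -4,
    "attack_level": 0.02,
    "attack_decay_ms": 50,
    "duration": 2,
    "sample_rate": 44100
  },
  "violin": {
    "label": "violin",
    "f0": 261.63,
    "partial_amps": [
      1,
      0.535887,
      0.372041,
      0.287175,
      0.234924,
      0.199372,
      0.173545,
      0.153893,
      0.138415,
      0.125893,
      0.115544,
      0.106841,
      0.099415,
      0.093,
      0.087401,
      0.082469,
      0.07809,
      0.074175,
      0.070652,
      0.067464,
      0.064566,
      0.061918,
      0.05949,
      0.057255,
      0.055189,
      0.053275,
      0.051496,
      0.049838,
      0.048288,
      0.046837,
      0.045475,
      0.044194,
      0.042987,
      0.041847,
      0.04077,
      0.039749,
      0.038781,
      0.037861,
      0.036986,
      0.036153
    ],
    "noise_level": 0.06,
    "noise_tilt_db_oct": -2,
    "attack_level": 0.03,
    "attack_decay_ms": 80,
    "duration": 2,
    "sample_rate": 44100
  },
  "piano": {
    "label": "piano",
    "f0": 261.63,
    "partial_amps": [
      1,
      0.287175,
      0.138415,
      0.082469,
      0.055189,
      0.039749,
      0.030118,
      0.023683,
      0.019159,
      0.015849,
      0.01335,
      0.011415,
      0.009883,
      0.008649,
      0.007639,
      0.006801,
      0.006098,
      0.005502,
      0.004992,
      0.004551,
      0.004169,
      0.003834,
      0.003539,
      0.003278,
      0.003046
    ],
    "noise_level": 0.02,
    "noise_tilt_db_oct": -4,
    "attack_level": 0.5,
    "attack_decay_ms": 150,
    "duration": 2,
    "sample_rate": 44100
  }
}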
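{
  "nodes": ["dT", "Treatment", "Growth", "dANB", "dIMPA", "dPPPM", "dCoA", "dGoPg", "dCoGo"],
  "sample_size": null,
  "binary_nodes": ["Treatment", "Growth"],
  "growth_rule": {
    "intercept": -1.4,
    "dT": 0.18,
    "Treatment": 0.6
  },
  "locals": {
    "dT": {
      "node": "dT",
      "parents": [],
      "intercept": 6.5,
      "coefficients": [],
      "residual_sd": 1.44337567297406
    },
    "Treatment": {
      "node": "Treatment",
      "parents": [],
      "intercept": 0.461538461538462,
      "coefficients": [],
      "residual_sd": 0.498518515262143
    },
    "Growth": {
      "node": "Growth",
      "parents": [
        "dT",
        "Treatment"
      ],
      "intercept": 0.150196887507912,
      "coefficients": {
        "dT": 0.0449752391164023,
        "Treatment": 0.149917463721341
      },
      "residual_sd": 0.499862420607479
    },
    "dANB": {
      "node": "dANB",
      "parents": [
        "Treatment"
      ],
      "intercept": -0.862748960964382,
      "coefficients": {
        "Treatment": 2
      },
      "residual_sd": 1.1407342037186
    },
    "dIMPA": {
      "node": "dIMPA",
      "parents": [
        "dANB",
        "dPPPM",
        "dT",
        "Growth"
      ],
      "intercept": 0.836435707286,
      "coefficients": {
        "dANB": -2.1238898485899,
        "dPPPM": 2.65687058400363,
        "dT": 3.44573001656681,
        "Growth": -3.80917452275753
      },
      "residual_sd": 1.12210524193943
    },
    "dPPPM": {
      "node": "dPPPM",
      "parents": [
        "dCoA",
        "Growth"
      ],
      "intercept": -1.11856976151466,
      "coefficients": {
        "dCoA": -3.23019787110388,
        "Growth": 2.18515417445451
      },
      "residual_sd": 0.880690969061106
    },
    "dCoA": {
      "node": "dCoA",
      "parents": [
        "dT",
        "Treatment"
      ],
      "intercept": -0.8878283649683,
      "coefficients": {
        "dT": 3.5097941942513,
        "Treatment": 2
      },
      "residual_sd": 1.07919068904594
    },
    "dGoPg": {
      "node": "dGoPg",
      "parents": [
        "dCoA",
        "dT",
        "Growth"
      ],
      "intercept": -0.925363004207611,
      "coefficients": {
        "dCoA": -2.1738421516493,
        "dT": -3.75684591848403,
        "Growth": 2.45286447089165
      },
      "residual_sd": 0.951834178343415
    },
    "dCoGo": {
      "node": "dCoGo",
      "parents": [
        "dANB",
        "dIMPA",
        "dT"
      ],
      "intercept": -0.137503117322922,
      "coefficients": {
        "dANB": -3.3325845869258,
        "dIMPA": 1.94522106088698,
        "dT": 3.20054630935192
      },
      "residual_sd": 0.933922664821148
    }
  }
}
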
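{
  "schema_version": 1,
  "beta0": -2.754,
  "beta1": -1.077,
  "beta2": -0.756,
  "beta3": 0.188,
  "beta4": 0.025,
  "beta5": -81.08,
  "beta6": -165.6,
  "beta7": -1174,
  "beta8": 0.218,
  "beta9": 0.164,
  "sigma_eps": 1.36,
  "provenance": "published-2015"
}
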
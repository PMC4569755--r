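{
  "schema_version": 1,
  "intercept": 8.71,
  "slope": 0.86,
  "ci_intercept": [3.31, 13.55],
  "ci_slope": [0.76, 0.95],
  "conf.level": 0.95,
  "n_pairs": 125,
  "scale": "original",
  "provenance": "published-2015"
}
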
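{
  "name": "fig2a",
  "description": "Adder with exponential growth: capacity increases monotonically with newborn size.",
  "law": {"kind": "exponential", "alpha": 0.020833333333333332},
  "rule": {"a": 1, "Vbar": 30, "Tmin": 20},
  "experiment": {"Tf": 72, "grid": {"lo": 3, "hi": 90, "n": 200}}
}
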
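{
  "name": "fig3c",
  "description": "Adder-timer mixture (a = 1.5) with a saturating growth rate: bell-shaped capacity from a monotone rate.",
  "law": {"kind": "saturating", "alpha": 0.020833333333333332, "Vth": 25},
  "rule": {"a": 1.5, "Vbar": 30, "Tmin": 20},
  "experiment": {"Tf": 72, "grid": {"lo": 3, "hi": 90, "n": 200}}
}
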
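{
  "name": "fig3a",
  "description": "Adder with a Hill-type non-monotonic growth rate (k = 3): bell-shaped capacity with an interior maximum.",
  "law": {"kind": "power_saturating", "alpha": 0.020833333333333332, "Vth": 20, "k": 3},
  "rule": {"a": 1, "Vbar": 30, "Tmin": 20},
  "experiment": {"Tf": 72, "grid": {"lo": 3, "hi": 90, "n": 200}}
}
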
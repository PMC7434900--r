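{
  "name": "fig3b",
  "description": "Sizer-adder mixture (a = 0.6) with the non-monotonic growth rate, grid extended to the clamp threshold (2-a)*Vbar/(1-a) = 105: bell-shaped capacity that rises again for very large newborns.",
  "law": {"kind": "power_saturating", "alpha": 0.020833333333333332, "Vth": 20, "k": 3},
  "rule": {"a": 0.6, "Vbar": 30, "Tmin": 20},
  "experiment": {"Tf": 72, "grid": {"lo": 3, "hi": 105, "n": 200}}
}
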
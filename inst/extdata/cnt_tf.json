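{
  "label": "end-capped CNT carrier, velocity-to-force",
  "a": -2.83e-10,
  "b": -1.18,
  "c": 1.67,
  "d": 0.95,
  "e": -0.24,
  "f": 0.97,
  "g": -1.99,
  "h": 0.99,
  "i": 1.69,
  "j": 0.98,
  "k": -0.24,
  "l": 0.99,
  "Ts": 1e-15,
  "input_units": "m/s",
  "output_units": "N",
  "Ts_units": "s"
}
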
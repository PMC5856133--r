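{
  "label": "fullerene (C720) carrier, velocity-to-force",
  "a": -4.6e-10,
  "b": -1.07,
  "c": 1.8,
  "d": 1.05,
  "e": -0.11,
  "f": 1.06,
  "g": -1.99,
  "h": 0.99,
  "i": 1.73,
  "j": 0.97,
  "k": -0.09,
  "l": 0.97,
  "Ts": 1e-15,
  "input_units": "m/s",
  "output_units": "N",
  "Ts_units": "s"
}
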
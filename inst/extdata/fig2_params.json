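{
  "D1": 0.28,
  "D2": 0.012061855670103093,
  "a": 150,
  "b": 156,
  "c": 0.1,
  "d": 0,
  "k": 0.005,
  "p": 0.01,
  "M": 0.1,
  "W": 1
}
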
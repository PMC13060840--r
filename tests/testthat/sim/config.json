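{
  "subcommand": "simulate",
  "kind": "hinge_pair",
  "n_res": 32,
  "seed": 1,
  "dr": 0.5
}
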
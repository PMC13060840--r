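{
  "max_residues": 256,
  "similarity_threshold": 70,
  "crop_length": 24,
  "pair_rmsd_min": 4,
  "conformer_rmsd_min": 2.5,
  "dr": 0.5,
  "seed": 3
}
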
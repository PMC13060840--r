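[2026-09-27 05:25:12] simulate: wrote fixtures under sim
[2026-09-27 05:25:38] simulate: wrote fixtures under sim
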
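[2026-09-27 05:25:12] curate: 1 entr(ies) retained
[2026-09-27 05:25:39] curate: 1 entr(ies) retained
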
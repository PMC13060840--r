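{"subcommand":"curate","n_input":3,"n_after_length":2,"n_final":1,"length_report":[{"entry":"t1","length":20,"kept":true,"reason":""},{"entry":"t2","length":30,"kept":true,"reason":""},{"entry":"t3","length":300,"kept":false,"reason":"length 300 > 256"}],"exclusion_report":[{"entry":"t1","max_identity":100,"closest_test":1,"kept":false,"_row":"test1"},{"entry":"t2","max_identity":20,"closest_test":1,"kept":true,"_row":"test11"}]}
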
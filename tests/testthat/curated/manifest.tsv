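entry_id	model_id	length	crop_start	crop_end	pr_path
t2	1	24	5	28	curated/t2_m1_pr.out
t2	2	24	5	28	curated/t2_m2_pr.out
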
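mirna	count_na	count_da
miR-10a	2973660	1482171
miR-10a-5p	2891589	1423173
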
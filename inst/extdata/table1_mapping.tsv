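category	unique_na	unique_da	reads_na	reads_da
miRNA	14687	20110	6782785	6715567
rRNA	17211	20960	162583	110189
snRNA	314	416	762	1368
snoRNA	43	43	90	74
tRNA	3989	5443	27147	125660
unann	525260	643447	3902881	4242070
total	561504	690419	10876248	11194928
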
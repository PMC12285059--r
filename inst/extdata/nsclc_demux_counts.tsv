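class	count
sample:CMO301	3208
sample:CMO302	3844
sample:CMO303	2243
sample:CMO304	2108
sample:CMO306	4840
sample:CMO307	6220
sample:CMO308	2342
multilabelled	7864
unlabelled	0
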
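class	count
sample:HTO_A	1918
sample:HTO_B	2001
sample:HTO_C	1876
sample:HTO_D	1726
sample:HTO_E	1493
sample:HTO_F	1545
sample:HTO_G	1833
sample:HTO_H	1874
multilabelled	2578
unlabelled	72
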
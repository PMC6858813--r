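gene	region	region_len
CBL	5UTR	142
SFN	3UTR	498
FOXA1	5UTR	312
TGFB1	3UTR	146
EPOR	5UTR	135
MAZ	5UTR	168
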
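proteome	n
HPA	12844
RetNet	331
AMD	158
Glaucoma	32
DR-G	172
DR+G	103
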
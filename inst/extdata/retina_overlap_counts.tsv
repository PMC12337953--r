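proteome	overlap	unique
RetNet	290	41
AMD	110	48
Glaucoma	22	10
DR-G	153	19
DR+G	97	6
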
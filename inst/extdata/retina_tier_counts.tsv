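proteome	HighlyDisordered	HighlyOrdered	ModeratelyDisordered	ModeratelyOrderedOrMildlyFlexible
HPA	7970	19	4371	459
RetNet	187	0	125	19
AMD	70	0	76	12
Glaucoma	14	0	17	1
DR-G	77	0	88	7
DR+G	48	0	55	0
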
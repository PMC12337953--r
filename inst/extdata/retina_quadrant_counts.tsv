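proteome	Q1	Q2	Q3	Q4
HPA	7396	3291	1671	461
RetNet	209	82	39	1
AMD	119	15	18	6
Glaucoma	23	5	1	3
DR-G	112	31	27	2
DR+G	73	20	9	1
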
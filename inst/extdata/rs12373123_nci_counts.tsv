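genotype	0	1	2	3	4	5	6	7	8	9	10	11	12	13
CC	6	7	19	7	0	1	0	0	0	1	0	0	1	1
CT	65	66	217	107	56	22	14	2	1	1	3	0	0	0
TT	132	218	539	308	132	43	27	6	6	4	2	1	0	0
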
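max_snps_per_locus	analysis	Oni	Omo	Oau	Oho	Oan	Oma	Oka	Sme	Sga	Tzi
1	denovo	1	0	0	0	0	0	1	0	3	0
2	denovo	1	2	0	1	0	0	1	1	6	25
3	denovo	4	11	0	3	1	0	2	1	11	67
4	denovo	10	19	1	6	1	0	4	4	21	142
5	denovo	19	47	7	8	2	0	5	14	45	280
1	reference	1	0	0	0	0	0	1	0	3	3
2	reference	1	4	0	1	0	0	1	3	8	39
3	reference	6	16	1	6	1	0	2	7	19	101
4	reference	15	29	3	8	3	0	5	12	33	214
5	reference	32	63	11	11	4	1	5	26	67	424
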
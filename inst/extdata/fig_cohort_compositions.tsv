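label	genotype	distance_kb	class	count	approximate
6.5kb-WT	WT	6.5	SSA	29	TRUE
6.5kb-WT	WT	6.5	EJ	1	TRUE
9.8kb-WT	WT	9.8	EJ	28	TRUE
9.8kb-WT	WT	9.8	aneuploid	1	TRUE
9.8kb-WT	WT	9.8	unrearranged	1	TRUE
12.3kb-WT	WT	12.3	EJ	28	TRUE
12.3kb-WT	WT	12.3	HR	1	TRUE
12.3kb-WT	WT	12.3	unrearranged	1	TRUE
18.2kb-WT	WT	18.2	EJ	28	TRUE
18.2kb-WT	WT	18.2	SSA	1	TRUE
18.2kb-WT	WT	18.2	unrearranged	1	TRUE
46.3kb-WT	WT	46.3	HR	21	TRUE
46.3kb-WT	WT	46.3	EJ	4	TRUE
46.3kb-WT	WT	46.3	SSA	2	TRUE
46.3kb-WT	WT	46.3	aneuploid	2	TRUE
46.3kb-WT	WT	46.3	unrearranged	1	TRUE
57.7kb-WT	WT	57.7	EJ	12	FALSE
57.7kb-WT	WT	57.7	HR	10	FALSE
57.7kb-WT	WT	57.7	SSA_plus_EJ	6	FALSE
57.7kb-WT	WT	57.7	unrearranged	2	FALSE
6.5kb-lif1	lif1	6.5	SSA	29	TRUE
6.5kb-lif1	lif1	6.5	HR	1	TRUE
9.8kb-lif1	lif1	9.8	aneuploid	20	TRUE
9.8kb-lif1	lif1	9.8	HR	10	TRUE
12.3kb-lif1	lif1	12.3	HR	27	TRUE
12.3kb-lif1	lif1	12.3	aneuploid	2	TRUE
12.3kb-lif1	lif1	12.3	unrearranged	1	TRUE
18.2kb-lif1	lif1	18.2	HR	27	TRUE
18.2kb-lif1	lif1	18.2	SSA	2	TRUE
18.2kb-lif1	lif1	18.2	unrearranged	1	TRUE
46.3kb-lif1	lif1	46.3	HR	22	TRUE
46.3kb-lif1	lif1	46.3	aneuploid	8	TRUE
57.7kb-lif1	lif1	57.7	HR	23	TRUE
57.7kb-lif1	lif1	57.7	unrearranged	7	TRUE
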
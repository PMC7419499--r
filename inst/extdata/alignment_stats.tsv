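sample	raw_reads	trimmed_reads	total_mapped	total_mapped_pct	unique_concordant	unique_concordant_pct
Lori_Bakhtiari_1	26282890	26282599	23596517	89.78	20652003	78.58
Lori_Bakhtiari_2	20075866	20075798	15466394	77.04	12798432	63.75
Lori_Bakhtiari_3	20428424	20428247	15572452	76.23	12591179	61.64
Lori_Bakhtiari_4	18061231	18061047	16009312	88.64	13402952	74.21
Zel_1	22292871	22292640	19240777	86.31	15964723	71.61
Zel_2	20164542	20164351	15486221	76.8	12547998	62.23
Zel_3	20532170	20532024	16542651	80.57	13214997	64.36
Zel_4	26926569	26926287	24459839	90.84	20622189	76.59
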
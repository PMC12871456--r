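nu_chrom	nu_start	nu_end	mt_start	mt_end	length	archaic_genomes	EUR	AFR	AMR	EAS	SAS	Papua
chr1	88592028	88592037	4524	4686	162	Denisovan	0	0	0	0	0	0
chr2	146676955	146676963	7954	8034	80	Denisovan	0	0	0	0	0	0
chr3	142815571	142815572	1378	1688	310	Denisovan/Chagyrskaya	0	0	0	0	0	3
chr4	82695010	82695012	11022	11188	166	Denisovan	6	29	5	1	14	1
chr4	178496733	178496733	5976	6018	42	Chagyrskaya	0	0	0	2	0	0
chr5	28004248	28004250	2824	2917	93	Denisovan/Chagyrskaya	0	0	0	0	0	0
chr9	85809246	85809253	1410	1473	63	Chagyrskaya/Vindija	0	15	1	0	0	0
chr11	49862017	49862019	16088	61	542	Vindija/Denisovan/Chagyrskaya	392	198	275	377	335	9
chr11	100145004	100145018	11498	11557	59	Chagyrskaya	42	0	24	8	30	3
chr21	21708297	21708298	5712	5820	108	Denisovan	122	145	95	162	127	12
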
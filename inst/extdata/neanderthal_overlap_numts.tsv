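nu_chrom	nu_start	nu_end	mt_start	mt_end	in_archaic	EUR	AFR	AMR	SAS	EAS
chr1	170256486	170256486	9801	10192	FALSE	0	0	0	4	0
chr1	37611748	37611748	8933	9007	FALSE	8	0	1	6	2
chr1	59195879	59195879	15420	15478	FALSE	0	4	0	0	0
chr1	61649661	61649662	5958	6076	FALSE	0	0	0	1	0
chr11	100145004	100145004	11498	11557	TRUE	39	0	18	28	6
chr11	49862017	49862017	16088	61	TRUE	34	1	9	8	0
chr11	99188486	99188490	9421	9487	FALSE	0	0	0	1	0
chr12	87959136	87959136	6483	6550	FALSE	0	0	0	1	0
chr15	51673831	51673832	4960	5631	FALSE	0	0	0	0	1
chr2	33667411	33667411	14776	15022	FALSE	5	0	5	11	3
chr2	34418573	34418876	5700	5820	FALSE	0	0	0	1	0
chr2	68801196	68801206	10191	16397	FALSE	1	0	0	0	0
chr2	79899154	79899154	7283	7381	FALSE	0	0	1	0	0
chr21	21708297	21708297	5712	5820	TRUE	0	0	0	1	0
chr3	17999761	17999761	12288	13613	FALSE	0	0	0	0	1
chr4	126419043	126419043	14030	14098	FALSE	0	0	2	0	7
chr4	178496733	178496733	5976	6018	TRUE	0	0	0	0	1
chr4	82695010	82695010	11022	11188	TRUE	1	1	1	0	0
chr5	32338477	32338477	14830	12714	FALSE	5	0	1	1	0
chr6	102877808	102877808	14641	14844	FALSE	0	0	0	0	1
chr6	68179572	68179572	7010	2699	FALSE	0	0	0	2	0
chr8	62102863	62102863	7083	8553	FALSE	0	1	0	0	0
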
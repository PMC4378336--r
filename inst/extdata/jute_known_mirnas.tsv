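group	family	name	length	count	sequence	homolog	matches	mismatches	gaps
Conserved	miR156	col-miR157a	21	5531609	UUGACAGAAGAUAGAGAGCAC	ath-miR157a	21	0	0
Conserved	miR156	col-miR156a	20	1724997	UGACAGAAGAGAGUGAGCAC	ath-miR156a	20	0	0
Conserved	miR166	col-miR166a	21	215636	UCGGACCAGGCUUCAUUCCCC	ath-miR166a	21	0	0
Conserved	miR167	col-miR167h	22	154973	UGAAGCUGCCAGCAUGAUCUUA	mdm-miR167h	22	0	0
Conserved	miR396	col-miR396b-3p	21	18695	GCUCAAGAAAGCUGUGGGAGA	gma-miR396b-3p	21	0	0
Conserved	miR168	col-miR168a	21	16590	UCGCUUGGUGCAGGUCGGGAA	ath-miR168a	21	0	0
Conserved	miR164	col-miR164a	21	7491	UGGAGAAGCAGGGCACGUGCA	ath-miR164a	21	0	0
Conserved	miR169	col-miR169b	21	2528	CAGCCAAGGAUGACUUGCCGG	ath-miR169b	21	0	0
Conserved	miR390	col-miR390a	21	2952	AAGCUCAGGAGGGAUAGCGCC	ath-miR390a	21	0	0
Conserved	mir160	col-miR160a-3p	21	1448	GCGUAUGAGGAGCCAAGCAUA	gma-miR160a-3p	21	0	0
Conserved	miR159	col-miR159a	21	484	UUUGGAUUGAAGGGAGCUCUA	ath-miR159a	21	0	0
Conserved	miR171	col-miR171b	21	558	UGAUUGAGCCGUGCCAAUAUC	osa-miR171b	21	0	0
Conserved	miR403	col-miR403	21	282	UUAGAUUCACGCACAAACUCG	ath-miR403	21	0	0
Conserved	miR398	col-miR398	21	262	GGAGCGACAUGAGAUCACAUG	hbr-miR398	20	1	0
Conserved	miR482	col-miR482b	22	2206	UCUUACCUACUCCACCCAUGCC	ghr-miR482b	21	1	0
Conserved	miR408	col-miR408	21	129	AUGCACUGCCUCUUCCCUGGC	ath-miR408	21	0	0
Conserved	miR397	col-miR397a	21	106	UCAUUGAGUGCAGCGUUGAUG	ath-miR397a	21	0	0
Conserved	miIR530	col-miR530a	21	81	UGCAUUUGCACCUGCACCUUU	csi-miR530a	20	1	0
Conserved	miR393	col-miR393b-3p	21	61	AUCAUGCGAUCCCUUCGGAAU	stu-miR393-3p	20	1	0
Conserved	miR394	col-miR394a	20	16	UUGGCAUUCUGUCCACCUCC	ath-miR394a	20	0	0
Conserved	miR827	col-miR827a	21	22	UUAGAUGACCAUCAACAAACA	ghr-miR827a	21	0	0
Conserved	miR477	col-miR477i	21	2	ACUCUCCCUCAAGGGCUUCCG	mes-miR477i	21	0	0
Conserved	miR2111	col-miR2111a	21	15	UAAUCUGCAUCCUGAGGUUUG	ptc-miR2111a	21	0	0
Conserved	miR172	col-miR172a	21	1480	AGAAUCUUGAUGAUGCUGCAU	ath-miR172a	21	0	0
Nonconserved	miR2275	col-miR2275a-3p	22	54	UUAAGUUUUCUCCAAUAUCUCA	zma-miR2275a-3p	20	1	2
Nonconserved	miR2118	col-miR2118a-3p	22	36	UUGCCGAAUCCGCCCAUUCCGU	gma-miR2118a-3p	19	2	1
Nonconserved	miR528	col-miR528-5p	21	17	UGGAAGGGGCAUGCAGAGGAG	osa-miR528-5p	21	0	0
Nonconserved	miR1310	col-miR1310	21	69	AGGCAUCGGGGGCGCAACGCC	han-miR1310	21	0	1
Nonconserved	miR7696	col-miR7696a-3p	21	6	UCUGAAUCAUGAGAACUUGAG	mtr-miR7696a-3p	19	1	2
Nonconserved	miR6224	col-miR6224a-3p	21	4	CUGAUAAUAUAGGACGGAGGG	sbi-miR6224a-3p	19	1	2
Nonconserved	miR6462	col-miR6462c-5p	21	28	AAGGGACAAAAAGGCUAUAAG	ptc-miR6462c-5p	20	0	3
Nonconserved	miR4243	col-miR4243	21	3	UUGAACUUGUACGAUUUCGAC	ath-miR4243	19	1	2
Nonconserved	miR5745	col-miR5745b	21	16	UUUAAUUUAUAUACAUCUCAC	mtr-miR5745b	20	0	2
Nonconserved	miR902	col-miR902j-5p	24	1	AUAUGUUACGCAGAUUCUUCAUUU	ppt-miR902j-5p	21	0	3
Nonconserved	miR2873	col-miR2873b	21	10	UUGUGGCUGAGAUUUGGUAUG	osa-miR2873b	19	1	2
Nonconserved	miR2950	col-miR2950	21	2465	UGGUGUGCAGGGGGUGGAAUA	ghr-miR2950	21	0	0
Nonconserved	miR5067	col-miR5049c	24	3837	GGACAAUUAUUGUGGGACGGAGGG	hvu-miR5049c	21	2	1
Nonconserved	miR818	col-miR1436	23	920	AGAUAAUAUGGGACGGAGGGAGU	osa-miR1436	20	1	2
Nonconserved	miR4414	col-miR4414a-3p	21	11	AUCCAACGAUGCAGGAGCUGC	mtr-miR4414a-3p	20	1	0
Nonconserved	miR1509	col-miR7122a	22	488	UUGGACAGAGAAAUCACGGUCG	mdm-miR7122a	20	2	0
Nonconserved	miR158	col-miR158a	20	34	UCCCAAAUGUAGACAAAGCA	ath-miR158a	20	0	0
Nonconserved	miR161	col-miR161.2	21	2	UCAAUGCAUUGAAAGUGACUA	ath-miR161.2	21	0	0
Undefined	Undefined	col-miR5162	24	4	AAAAUGACCAAAAUACCCCUAAAU	osa-miR5162	22	1	2
Undefined	Undefined	col-miR6248	20	1	UAAUUGAGGAUGGAGGGAGU	osa-miR6248	18	2	1
Undefined	Undefined	col-miR7767-3p	22	1	UAGGAUCAGGCAGCUUGAAGGU	bdi-miR7767-3p	19	2	1
Undefined	Undefined	col-miR5997	21	1	UGAAACUCAAGUAGCUAAAAG	ath-miR5997	20	0	2
Undefined	Undefined	col-miR5057	23	1	AAACUUUCAGAUGCAUUUUGACA	bdi-miR5057	20	1	2
Undefined	Undefined	col-miR6172	21	1	UGAGACCUGUUUAAGUUAGAA	hbr-miR6172	19	1	2
Undefined	Undefined	col-miR6279	20	3	UAACAAGAAUUCCAGACACA	ppe-miR6279	18	2	1
Undefined	Undefined	col-miR6220-3p	23	1	AGACUUAUAAUUUGGGACGGAGA	sbi-miR6220-3p	21	2	1
Undefined	Undefined	col-miR6443	21	1	UGUAUGAUCAUGAUGCUGGAG	ptc-miR6443	19	1	2
Undefined	Undefined	col-miR156h	20	17	UGACAGAAGAGAGAGAGCAU	vvi-miR156h	20	0	0
Undefined	Undefined	col-miR3954	22	868222	UUGGACAGAGUAAUCACGGUCG	csi-miR3954	19	2	1
Undefined	Undefined	col-miR167i	20	1	UCAUGCUGGCAGCUUCACUU	gma-miR167i	20	0	3
Undefined	Undefined	col-miR6300	19	4400	GUCGUUGUAGUAUAGUGGU	gma-miR6300	18	0	1
Undefined	Undefined	col-miR169p	21	6	UAGCCAAGGACAACUUGCCGG	osa-miR169p	21	0	1
Undefined	Undefined	col-miR894	20	5406	GUUUCACGUCGGGUUCACCA	ppt-miR894	19	0	2
Undefined	Undefined	col-miR472a	22	218	UUUUCCCUACUCCUCCCAUCCC	ptc-miR472a	21	1	0
Undefined	Undefined	col-miR5059	21	212	CGGUCCUGGGCAGCAACACCA	bdi-miR5059	19	1	1
Undefined	Undefined	col-miR2916	22	312	GGGGGCUCGAAGACGAUCAGAU	peu-miR2916	20	2	1
Undefined	Undefined	col-miR5072	21	90	CGUUCCCCAGCGGAGUCGCCA	osa-miR5072	21	0	1
Undefined	Undefined	col-miR477h	22	4	ACUCUCCCUCAAGGGCUUCCAG	mes-miR477h	21	0	1
Undefined	Undefined	col-miR6478	21	164	CCGACCUUAGCUCAGUUGGUA	ptc-miR6478	20	1	0
Undefined	Undefined	col-miR5205b	24	306	CUUAUAAUUAGGGACAGAGGGAGU	mtr-miR5205b	23	1	0
Undefined	Undefined	col-miR7505	21	31	UUCAGAAACCAUCCCCUCCUU	ghr-miR7505	20	1	0
Undefined	Undefined	col-miR5077	20	378	GAUUCACGUCGGGUUCACCA	osa-miR5077	18	1	1
Undefined	Undefined	col-miR5054	20	904	GUUCCCCACAGUCGGCGCCA	bdi-miR5054	17	1	2
Undefined	Undefined	col-miR845c	24	28	AGGCUCUGAUACCAAUUGACGUAG	vvi-miR845c	21	0	3
Undefined	Undefined	col-miR916	22	28	CGAAGGUCGUCGGUUCGAAUCC	cre-miR916	19	2	1
Undefined	Undefined	col-miR161-5p.1	21	11	UUGAAAGUGACUACAUCGGGG	aly-miR161-5p.1	21	0	0
Undefined	Undefined	col-miR1863	24	56	AGCUCUGAUACCAUGUUAAGCAUC	pab-miR1863	21	1	2
Undefined	Undefined	col-miR7490	24	41	AGUCUGAUAAACUCCACUGACGGU	ghr-miR7490	22	1	2
Undefined	Undefined	col-miR3946	21	13	UUGAGAGAAGAGAGAGAGCAC	csi-miR3946	21	0	3
Undefined	Undefined	col-miR7728-5p	19	5	UUCGGAUUGAGUGGAUUUU	bdi-miR7728-5p	18	1	2
Undefined	Undefined	col-miR1862f	21	1	AAGGGGUUGGUUUACUUUUGG	osa-miR1862f	18	2	1
Undefined	Undefined	col-miR6171	21	11	ACUAUGGAUUGCUGAAGGUUU	hbr-miR6171	19	1	2
Undefined	Undefined	col-miR5021	21	31	UAAGAAGAAUAAGAAGAAUAA	ath-miR5021	18	2	1
Undefined	Undefined	col-miR5244	21	6	UAUCUGAUGAUGAUUGUUGGU	mtr-miR5244	19	2	0
Undefined	Undefined	col-miR5049-3p	23	30	AAGUAAUAUGGAACGGAGGGAGU	bdi-miR5049-3p	21	2	1
Undefined	Undefined	col-miR5629	23	41	UUAGGGUAGUUAACGGGUAGUUA	ath-miR5629	21	1	1
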
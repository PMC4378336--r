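name	reads	sequence	length	mfe
col-miRN1-5p	1448	GUGGGCGUGCCGGAGUGGUUA	21	-28.9
col-miRN2-3p	219	AGAGGGACUAUGGCCGCUUA	20	-53.5
col-miRN3-3p	17	UCGGUUUUGAAUUAGAGACGU	21	-85
col-miRN4-3p	14	UGAUGAUUGUGAAGAAGAUGA	21	-66.34
col-miRN5-3p	32	AGAGGCUCGGUGAAAUAGACAU	22	-24.62
col-miRN6-5p	11	UUCGUCCCCGGCAACGGCGCCA	22	-66.6
col-miRN7-5p	7	UUUUUUAAUUUUUUAUUUAUC	21	-21
col-miRN8-5p	20	GUUGAUCAAGUUGUGGAUGGC	21	-79.32
col-miRN9-3p	2	AAACUUCGAAUUGGGAGGGC	20	-89.3
col-miRN10-3p	3	UGAAUGAUUUCGGACCAGGCU	21	-48.3
col-miRN11-3p	2	GUAAGAAGGGGUAGAGAAAAU	21	-34.9
col-miRN12-3p	5	AAGAUAGAGAGCACAGAUGAU	21	-51.1
col-miRN13-5p	3	GGCGCUGCCUACUCACUCGGACA	23	-40.77
col-miRN14-3p	7	GUGAGGCUGGUUUCACAGAGCA	22	-39.1
col-miRN15-5p	6	GAGUGCAGCCAAGGAUGACUU	21	-64.9
col-miRN16-5p	4	UCAAGGUGGAGAUUGUUAGGA	21	93.4
col-miRN17-5p	6	UUAUACGAUGUGGGAUAUUAC	21	-105.3
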
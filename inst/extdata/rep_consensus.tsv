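family_id	host	variant_index	sequence	n_exact	n_le1	n_le2	rayt_bime
Ckos	Citrobacter koseri ATCC BAA-895	0	GTAGGCCcGgTAAGCGaaGCGCCaCCgGGC	9	46	77	N
Ckos	Citrobacter koseri ATCC BAA-895	1	GTAGGCCgGaTAAgGCGcttGCGCCgCCatccGGC	16	23	65	N
Esak	Enterobacter sakazakii ATCC BAA-894	0	GTAGGGcGGGTAAGCGgAGCGCACCCgCC	3	89	159	N
Esak	Enterobacter sakazakii ATCC BAA-894	1	GTAGGGtGGGTAAGCGcAGCGCACCCaCC	39	117	180	N
Ecol	Escherichia coli str. K-12 substr. MG1655	0	GTAGGacgGATAAGgCGttCACGcCGCATCcGGCA	4	52	126	Y
Ecol	Escherichia coli str. K-12 substr. MG1655	1	GTAGGcatGATAAGaCGcgcCAgCGtCGCATCaGGCA	4	19	46	Y
Sent	Salmonella enterica subsp. enterica serovar Typhi str. CT18	0	TGTAGGCCGGATAAGgcgtagcCGCCATCCGGCT	1	10	16	N
Sent	Salmonella enterica subsp. enterica serovar Typhi str. CT18	1	GTAGGCCGGATAAGcaacgCGCCATCCGGC	1	2	6	N
Kpne	Klebsiella pneumoniae 342	0	GTAGGCCcggcAAGCGcAGCGCCgccgGGC	8	12	20	Y
Kpne	Klebsiella pneumoniae 342	1	GTAGGCCggatAAgGCGaAGcCGCCatccGGC	2	11	13	Y
Hpar	Haemophilus parasuis SH0165	0	GTAGGGTGGGTCTTGACCCACC	20	22	42	N
Hinf	Haemophilus influenzae Rd KW20	0	GTAGGGTGGGCTTcAGCCCACC	6	14	21	Y
Hinf	Haemophilus influenzae Rd KW20	1	GTAGGGTGGGCTTtAGCCCACC	5	16	21	Y
Cbur	Coxiella burnetii Dugway 5J108-111	0	GTAGGTTGGGCTGAGCTTGCGAAGCCCAAC	29	38	40	N
T_sp	Thioalkalivibrio sp. HL-EbGR7	0	GTAGGTCGGCCTTCAGGCCGAC	38	53	118	N
Pmen	Pseudomonas mendocina ymp	0	GTAGCCCGGATGCAATCCGGG	75	136	162	N
Pput1	Pseudomonas putida KT2440	0	TGTGGGAGCGGGCgTGCCCGCGAAT	62	193	286	N
Pput1	Pseudomonas putida KT2440	1	GTGGGAGCGGGCaTGCCCGCGAA	35	172	285	N
Pput2	Pseudomonas putida GB-1	0	TGTGGGAGCGGGTTtACCCGCGAAT	62	95	130	N
Pput2	Pseudomonas putida GB-1	1	GTGGGAGCGGGTTcACCCGCGAA	14	80	104	N
Pput3	Pseudomonas putida KT2440	0	TGTGGGAGCGGCCTTGcGTCGCGAT	21	53	69	N
Pput3	Pseudomonas putida KT2440	1	GTGGGAGCGGCCTTGtGTCGCGA	27	62	72	N
Pput4	Pseudomonas putida W619	0	TGTAGGAGCGGCCTTGcGTCGCGAAT	24	112	189	Y
Pput4	Pseudomonas putida W619	1	GTAGGAGCGGCCTTGtGTCGCGAA	77	174	205	Y
Pent1	Pseudomonas entomophila L48	0	TGTAGGAGCGGATTCATCCGCGAT	116	171	443	N
Pent2	Pseudomonas entomophila L48	0	GTAGGAGCCAGCTTGCTGGCGAA	89	101	564	N
Pflu1	Pseudomonas fluorescens SBW25	0	GTGGGAGGGGGCTTGCCCCCGAT	387	557	607	N
Pflu2	Pseudomonas fluorescens SBW25	0	GTGGCGAGGGAGCTTGCTCCCGCT	104	192	232	Y
Pflu3	Pseudomonas fluorescens SBW25	0	TGTgGTGAGCGGGCTTGCCCCGCGCTT	83	217	263	Y
Pflu3	Pseudomonas fluorescens SBW25	1	GTaGTGAGCGGGCTTGCCCCGCGCT	119	229	257	Y
Xaxo	Xanthomonas axonopodis pv. citri str. 306	0	GTAGGAGCGCACCtGGGCGCGAC	9	49	85	Y
Xaxo	Xanthomonas axonopodis pv. citri str. 306	1	GTAGGAGCGCACCcGGGCGCGAC	23	58	88	Y
Xcam	Xanthomonas campestris pv. campestris str. ATCC 33913	0	GTAGGAGCGCGCTCGCGCGCGA	48	177	223	Y
Smal1	Stenotrophomonas maltophilia R551-3	0	TGTAGAGCCGAGCCCATGCTCGGCT	49	90	113	N
Smal2	Stenotrophomonas maltophilia R551-3	0	GGTAGCGCCGGGCCATGCCCGGCG	259	329	355	N
Smal3	Stenotrophomonas maltophilia K279a	0	GGTGGGTGCCGACCGTTGGTCGGCAC	52	75	99	N
Smal4	Stenotrophomonas maltophilia K279a	0	GGTAGTGCCGGCCGCTGGCCGGCA	427	556	644	Y
S_sp1	Stenotrophomonas sp. SKA14	0	AGTAGATCCACGCCATGCGTGGAT	69	147	182	N
S_sp2	Stenotrophomonas sp. SKA14	0	GGTGGGTGCCAACCTTGGTTGGCAC	37	84	131	N
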
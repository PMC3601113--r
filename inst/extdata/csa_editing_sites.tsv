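gene	region	strand	pos	ref	A	C	G	U	codon_change	aa_change
matK	CDS	-	2314	G	21	0	1	0	CAT -> TAT	H -> Y
matK	CDS	-	2847	G	11	0	4	0	TCT -> TTT	S -> F
matK	CDS	-	3103	G	11	0	0	0	CAC -> TAC	H -> Y
rps16	intron	-	5699	G	14	0	0	0		
psbK - psbI	IGS	+	8518	C	0	28	0	29		
atpA	CDS	-	11607	G	100	0	3	0	TCA -> TTA	S -> L
atpA	CDS	-	11730	G	196	0	4	0	CCA -> CTA	P -> L
atpF	CDS	-	13759	G	89	0	27	0	CCA -> CTA	P -> L
rps2	CDS	-	16993	G	231	0	2	0	TCA -> TTA	S -> L
rps2	CDS	-	17107	G	65	0	39	0	ACA -> ATA	T -> I
rpoC2	CDS	-	17896	G	178	0	24	0	TCA -> TTA	S -> L
rpoC2	CDS	-	18775	G	14	0	3	0	TCT -> TTT	S -> F
rpoC1	CDS	-	23350	G	9	0	5	0	TCA -> TTA	S -> L
rpoC1	CDS	-	24541	G	13	0	10	0	TCA -> TTA	S -> L
rpoB	CDS	-	25821	G	13	0	2	0	TCT -> TTT	S -> F
psbZ	CDS	+	37874	C	0	45	0	138	TCA -> TTA	S -> L
rps14	CDS	-	38898	G	346	0	50	0	CCA -> CTA	P -> L
rps14	CDS	-	38967	G	326	1	26	0	TCA -> TTA	S -> L
ycf3	intron	-	45008	G	46	0	9	0		
trnL-UAA	intron	-	49664	G	0	0	16	60		
ndhK	CDS	-	52696	G	8	0	4	0	TCA -> TTA	S -> L
accD	CDS	+	60548	C	0	9	0	30	CCT -> CTT	P -> L
psaI	CDS	+	61442	C	0	1	0	12	TCT -> TTT	S -> F
psaI	CDS	+	61447	C	0	3	0	7	CAT -> TAT	H -> Y
psbF	CDS	-	66717	G	88	0	15	21	TCT -> TTT	S -> F
psbE	CDS	-	66841	G	137	0	10	0	CCT -> CTT	P -> L
trnW-CCA	tRNA	-	68908	G	16	0	0	0		
rps18	CDS	+	70757	C	0	9	0	29	TCG -> TTG	S -> L
petB	CDS	+	78772	C	0	18	0	133	CCA -> CTA	P -> L
ndhF	CDS	-	114757	G	12	0	4	0	TCA -> TTA	S -> L
ndhH	CDS	-	125218	G	75	0	8	0	TCA -> TTA	S -> L
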
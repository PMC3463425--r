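gene_id	operon_id	group	strand	cre_sequence	fc_low	fc_med	fc_high	sig_low	sig_med	sig_high	dist_tss	score_printed
acoR	acoR	high	upper	TGAAAGCGCTTTAT	-4.8	-18.7	-21.7	TRUE	TRUE	TRUE	-27	5
acsA	acsA	high	lower	TGAAAGCGTTACCA	-2.3	-2.5	-2.7	TRUE	TRUE	TRUE	44	4
acuA	acuA	high	upper	TGAAAACGCTTTAT	-2.2	-4.6	-7.7	TRUE	TRUE	TRUE	-26	4
amyE	amyE	high	upper	TGTAAGCGTTAACA	-2.6	-10.7	-12.9	TRUE	TRUE	TRUE	4	5
bglP	bglP	high	lower	TGAAAGCGTTGACA	-2.5	-4.7	-4.6	TRUE	TRUE	TRUE	-36	4
cccA	cccA	high	lower	TGTAAGCGTATACA	-2.2	-1.8	-2.8	TRUE	TRUE	TRUE	-29	5
citM	citM	high	upper	TGTAAGCGGATTCA	-2.6	-2.7	-2.9	TRUE	TRUE	TRUE	46	4
cstA	cstA	high	lower	TGAATGCGGTTACA	-2.2	-1.9	-2.4	TRUE	TRUE	TRUE	32	4
dctP	dctP	high	upper	TGAAAACGCTATCA	-7.4	-12.3	-16.6	TRUE	TRUE	TRUE	-14	5
glpF	glpF	high	upper	TGACACCGCTTTCA	-4.3	-21.9	-35.6	TRUE	TRUE	TRUE	-27	5
gmuB	gmuB	high	upper	TGTAAGCGTTTTAA	-3.0	-15.6	-35.8	TRUE	TRUE	TRUE	6	4
iolA-1	iol	high	lower	TGAAAGCGTTTAAT	-1.8	-1.9	-2.1	TRUE	TRUE	TRUE	93	3
iolA-2	iol	high	lower	TGAAAACGTTGTCA	-2.2	-2.5	-2.4	TRUE	TRUE	TRUE	2404	6
manR	manR	high	upper	TGTAAACGGTTTCT	-2.0	-3.7	-8.0	TRUE	TRUE	TRUE	0	4
msmX	msmX	high	lower	AGAAAGCGTTTACA	-2.0	-2.6	-3.1	TRUE	TRUE	TRUE	-15	4
rbsR	rbsR	high	upper	TGTAAACGGTTACA	-6.7	-15.2	-23.1	TRUE	TRUE	TRUE	6	6
rocG	rocG	high	lower	TTAAAGCGCTTACA	-2.6	-3.5	-3.1	TRUE	TRUE	TRUE	43	5
sacP	sacP	high	lower	CGAAAACGCTATCA	-2.1	-7.9	-8.1	TRUE	TRUE	TRUE	-19	4
sucC	sucC	high	upper	TGAAAGCGCAGTCT	-2.0	-5.8	-3.4	TRUE	TRUE	TRUE	0	4
treP	treP	high	upper	TGAAAACGCTTGCA	-3.2	-13.0	-17.5	TRUE	TRUE	TRUE	372	5
uxaC	uxaC	high	upper	TGAAAGCGTTATCA	-2.5	-3.7	-8.9	TRUE	TRUE	TRUE	1237	5
xsa	xsa	high	lower	TAAAAGCGCTTACA	-1.9	-1.8	-2.6	TRUE	TRUE	TRUE	7	5
xylA	xylA	high	upper	TGGAAGCGCAAACA	-2.4	-11.9	-11.1	TRUE	TRUE	TRUE	144	4
xynP	xynP	high	upper	TGAAAGCGCTTTTA	-4.0	-11.0	-17.9	TRUE	TRUE	TRUE	230	6
yisS	yisS	high	upper	AGAAAACGCTTTCT	-1.9	-3.5	-3.7	TRUE	TRUE	TRUE	74	6
yjmD	yjmD	high	upper	TGAAAGCGGTTCAA	-2.2	-2.4	-8.8	TRUE	TRUE	TRUE	ND	4
ykoM	ykoM	high	upper	TGCAAGGGCTTTCA	-2.0	-3.4	-3.5	TRUE	TRUE	TRUE	150	5
yrpD	yrpD	high	upper	TGATAGCGTTTTCT	-1.9	-8.0	-6.8	TRUE	TRUE	TRUE	127	4
ytkA	ytkA	high	lower	TGTAAGCGTTTGCT	-1.9	-6.4	-6.8	TRUE	TRUE	TRUE	ND	4
yulD	yulD	high	lower	TGAAAGCGCTATCT	-2.3	-4.9	-5.3	TRUE	TRUE	TRUE	ND	5
yvfK	yvfK	high	lower	TTAAAGCGCTTTCA	-4.0	-6.1	-10.6	TRUE	TRUE	TRUE	5	6
abnA	abnA	low	lower	TGTAAGCGCTTTCT	-1.8	-1.7	-2.5	FALSE	FALSE	TRUE	85	5
acoA	acoA	low	lower	TGTAAGCGTTTGCT	-1.1	-1.0	-1.8	FALSE	FALSE	TRUE	462	4
citZ	citZ	low	lower	TGTAAGCATTTTCT	-1.5	-1.8	-2.1	FALSE	TRUE	TRUE	88	3
csbX	csbX	low	lower	TGAAAACGGTGCCA	-1.4	-2.8	-2.1	FALSE	TRUE	TRUE	-401	4
cydA	cydA	low	lower	TGAAATGAATCGTT	1.6	1.0	-2.7	FALSE	FALSE	TRUE	-21	2
drm	drm	low	lower	TGAAAACGGTTTAT	-1.3	-3.6	-3.2	FALSE	TRUE	TRUE	-16	4
gntR-1	gntR	low	upper	TGAAAGTGTTTGCA	-1.3	-2.8	-3.2	FALSE	TRUE	TRUE	-41	4
gntR-2	gntR	low	upper	TGAAAGCGGTACCA	-1.3	-2.8	-3.2	FALSE	TRUE	TRUE	148	4
hutP	hutP	low	upper	TGAAACCGCTTCCA	-1.3	-1.9	-2.6	FALSE	TRUE	TRUE	209	5
lcfA	lcfA	low	lower	TGAAAACGTTATCA	-1.4	-2.6	-2.6	FALSE	TRUE	TRUE	450	6
levD	levD	low	lower	TGAAAACGCTTAAC	-1.5	-1.2	-2.2	FALSE	FALSE	TRUE	-45	3
malA	malA	low	upper	TGTAAACGTTATCA	-1.7	-2.0	-2.6	FALSE	TRUE	TRUE	6	5
mleN	mleN	low	lower	TGAAAGCGTTTTAG	-1.5	-3.5	-2.4	FALSE	TRUE	TRUE	21	4
msmR	msmR	low	upper	TGTAACCGCTTACT	-1.7	-4.2	-12.2	FALSE	TRUE	TRUE	-28	5
mtlR	mtlR	low	upper	TGAAAGCGTTTTAT	-1.5	-2.7	-2.5	FALSE	TRUE	TRUE	-16	4
odhA	odhA	low	lower	TGGAAGCGTTTTTA	-1.6	-6.6	-3.4	FALSE	TRUE	TRUE	21	4
pbuG	pbuG	low	upper	TGAAAACGTTTTTT	-1.1	-1.5	-1.9	FALSE	FALSE	TRUE	245	5
pta	pta	low	lower	TGAAAGCGCTATAA	1.3	-3.2	-2.7	FALSE	TRUE	TRUE	-55	5
resA	resA	low	lower	TAAAAACGCTTTCT	-1.1	-1.9	-1.9	FALSE	TRUE	TRUE	-72	4
sigL	sigL	low	lower	GGAAAACGCTTTCA	-1.1	-3.1	-3.3	FALSE	TRUE	TRUE	ND	5
wprA	wprA	low	upper	TGTAAGCGGTATCT	-1.6	-5.5	-4.2	FALSE	TRUE	TRUE	43	3
yckB	yckB	low	lower	TGAAAACGCGATCA	-1.4	-3.5	-2.1	FALSE	TRUE	TRUE	-48	4
ycsA	ycsA	low	upper	AGAAAGCGCTTACG	-1.7	-6.0	-10.3	FALSE	TRUE	TRUE	67	5
ydzA	ydzA	low	lower	TGAAAACGTGTCCA	-1.3	-6.4	-6.4	FALSE	TRUE	TRUE	9	5
yesL	yesL	low	upper	TGAAAGCGTTTTCC	-1.3	-1.6	-2.0	FALSE	FALSE	TRUE	125	4
yfiG	yfiG	low	upper	AGAAAGCGGTTACA	-1.6	-2.7	-4.6	FALSE	TRUE	TRUE	38	4
yncC	yncC	low	upper	TGTAAACGGTTACA	-1.3	-2.4	-3.8	FALSE	TRUE	TRUE	84	6
yojA	yojA	low	lower	TGAAAGCGCTTTCT	1.1	-1.5	-1.8	FALSE	FALSE	TRUE	57	6
yqgW	yqgW	low	upper	TGAAAACGCTATCG	-1.1	-4.5	-4.2	FALSE	TRUE	TRUE	-39	4
yqgY	yqgY	low	upper	TGAAAATGTTTACA	-1.4	-5.4	-4.1	FALSE	TRUE	TRUE	-38	5
ysbA	ysbA	low	lower	TGTAAGCGCTTTAT	1.0	-3.8	-7.6	FALSE	TRUE	TRUE	ND	4
ysfC	ysfC	low	upper	TGAAAGCGTTTTTT	-1.5	-1.5	-2.0	FALSE	FALSE	TRUE	196	4
yugN	yugN	low	lower	TGAATGCGCTTTCT	-1.7	-2.4	-2.3	FALSE	TRUE	TRUE	ND	5
yuxG	yuxG	low	lower	TGAAAACGGATACA	-1.2	-4.2	-6.1	FALSE	TRUE	TRUE	0	4
yvdG	yvdG	low	lower	TGTAACCGCTTTCT	-1.4	-1.5	-2.1	FALSE	FALSE	TRUE	-28	5
yxlH	yxlH	low	upper	TTGAAACGCTTTCA	-1.4	-2.0	-2.3	FALSE	TRUE	TRUE	260	4
yydK	yydK	low	upper	TGTAAGCGGTTTAT	-1.5	-3.2	-2.4	FALSE	TRUE	TRUE	-21	3
yyzE	yyzE	low	lower	TGAAAGCGTAACCA	-1.2	-3.0	-2.1	FALSE	TRUE	TRUE	0	3
ilvB	ilvB	activating	lower	TGAAAGCGTATACA	3.0	6.2	2.7	TRUE	TRUE	TRUE	88	NA
opuE	opuE	activating	lower	TGAAAGCGTTTTAT	2.3	2.5	2.3	TRUE	TRUE	TRUE	-103	NA
ycbP	ycbP	activating	lower	TGAAAGCGCTCGCT	2.5	3.3	2.6	TRUE	TRUE	TRUE	30	NA
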
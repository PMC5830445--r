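##gff-version 3
contig_1	rumag	CDS	1	900	.	+	0	ID=demoMAG_contig_1_g01
contig_1	rumag	CDS	1001	1900	.	+	0	ID=demoMAG_contig_1_g02
contig_1	rumag	CDS	2001	2900	.	+	0	ID=demoMAG_contig_1_g03
contig_1	rumag	CDS	3001	3900	.	+	0	ID=demoMAG_contig_1_g04
contig_1	rumag	CDS	4001	4900	.	+	0	ID=demoMAG_contig_1_g05
contig_1	rumag	CDS	5001	5900	.	+	0	ID=demoMAG_contig_1_g06
contig_1	rumag	CDS	6001	6900	.	+	0	ID=demoMAG_contig_1_g07
contig_1	rumag	CDS	7001	7900	.	+	0	ID=demoMAG_contig_1_g08
contig_1	rumag	CDS	8001	8900	.	+	0	ID=demoMAG_contig_1_g09
contig_1	rumag	CDS	9001	9900	.	+	0	ID=demoMAG_contig_1_g10
contig_1	rumag	CDS	10001	10900	.	-	0	ID=demoMAG_contig_1_g11
contig_1	rumag	CDS	11001	11900	.	-	0	ID=demoMAG_contig_1_g12
contig_1	rumag	CDS	12001	12900	.	+	0	ID=demoMAG_contig_1_g13
contig_1	rumag	CDS	13001	13900	.	+	0	ID=demoMAG_contig_1_g14
contig_1	rumag	CDS	14001	14900	.	+	0	ID=demoMAG_contig_1_g15
contig_1	rumag	CDS	15001	15900	.	+	0	ID=demoMAG_contig_1_g16
contig_1	rumag	CDS	16001	16900	.	+	0	ID=demoMAG_contig_1_g17
contig_1	rumag	CDS	17001	17900	.	+	0	ID=demoMAG_contig_1_g18
contig_1	rumag	CDS	18001	18900	.	+	0	ID=demoMAG_contig_1_g19
contig_1	rumag	CDS	19001	19900	.	+	0	ID=demoMAG_contig_1_g20
contig_1	rumag	CDS	20001	20900	.	+	0	ID=demoMAG_contig_1_g21
contig_1	rumag	CDS	21001	21900	.	+	0	ID=demoMAG_contig_1_g22
contig_1	rumag	CDS	22001	22900	.	+	0	ID=demoMAG_contig_1_g23
contig_1	rumag	CDS	23001	23900	.	+	0	ID=demoMAG_contig_1_g24
contig_1	rumag	CDS	24001	24900	.	+	0	ID=demoMAG_contig_1_g25
contig_1	rumag	CDS	25001	25900	.	+	0	ID=demoMAG_contig_1_g26
contig_1	rumag	CDS	26001	26900	.	+	0	ID=demoMAG_contig_1_g27
contig_1	rumag	CDS	27001	27900	.	+	0	ID=demoMAG_contig_1_g28
contig_2	rumag	CDS	1	900	.	+	0	ID=demoMAG_contig_2_g01
contig_2	rumag	CDS	1001	1900	.	+	0	ID=demoMAG_contig_2_g02
contig_2	rumag	CDS	2001	2900	.	+	0	ID=demoMAG_contig_2_g03
contig_2	rumag	CDS	3001	3900	.	+	0	ID=demoMAG_contig_2_g04
contig_2	rumag	CDS	4001	4900	.	+	0	ID=demoMAG_contig_2_g05
contig_2	rumag	CDS	5001	5900	.	+	0	ID=demoMAG_contig_2_g06
contig_2	rumag	CDS	6001	6900	.	+	0	ID=demoMAG_contig_2_g07
contig_2	rumag	CDS	7001	7900	.	+	0	ID=demoMAG_contig_2_g08
contig_2	rumag	CDS	8001	8900	.	+	0	ID=demoMAG_contig_2_g09
contig_2	rumag	CDS	9001	9900	.	+	0	ID=demoMAG_contig_2_g10
contig_2	rumag	CDS	10001	10900	.	+	0	ID=demoMAG_contig_2_g11
contig_2	rumag	CDS	11001	11900	.	+	0	ID=demoMAG_contig_2_g12
contig_2	rumag	CDS	12001	12900	.	+	0	ID=demoMAG_contig_2_g13
contig_2	rumag	CDS	13001	13900	.	+	0	ID=demoMAG_contig_2_g14
contig_2	rumag	CDS	14001	14900	.	+	0	ID=demoMAG_contig_2_g15
contig_2	rumag	CDS	15001	15900	.	+	0	ID=demoMAG_contig_2_g16
contig_2	rumag	CDS	16001	16900	.	+	0	ID=demoMAG_contig_2_g17
contig_2	rumag	CDS	17001	17900	.	+	0	ID=demoMAG_contig_2_g18
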
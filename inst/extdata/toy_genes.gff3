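##gff-version 3
chrT	toy	gene	1001	2000	.	+	.	ID=geneA
chrT	toy	exon	1001	1200	.	+	.	Parent=geneA
chrT	toy	exon	1501	1800	.	+	.	Parent=geneA
chrT	toy	exon	1901	2000	.	+	.	Parent=geneA
chrT	toy	CDS	1101	1200	.	+	0	Parent=geneA
chrT	toy	CDS	1501	1800	.	+	2	Parent=geneA
chrT	toy	CDS	1901	1959	.	+	2	Parent=geneA
chrT	toy	gene	3001	4000	.	-	.	ID=geneB
chrT	toy	exon	3001	4000	.	-	.	Parent=geneB
chrT	toy	CDS	3201	3800	.	-	0	Parent=geneB
chrT	toy	gene	5001	5600	.	+	.	ID=geneC
chrT	toy	exon	5001	5200	.	+	.	Parent=geneC
chrT	toy	exon	5401	5600	.	+	.	Parent=geneC
chrT	toy	CDS	5101	5200	.	+	0	Parent=geneC
chrT	toy	CDS	5401	5501	.	+	2	Parent=geneC
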
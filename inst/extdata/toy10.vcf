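##fileformat=VCFv4.2
##source=popgenscan
##contig=<ID=chr1,length=100000>
##contig=<ID=chr2,length=50000>
##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	A1	A2	B1
chr1	101	.	A	G	55.2	.	DP=61	GT:DP	0/0:21	0/1:18	1/1:25
chr1	250	.	C	T	43	.	DP=58	GT:DP	0/1:19	0/1:22	0/0:17
chr1	388	.	G	A	61.5	.	DP=70	GT:DP	1/1:24	0/1:20	0/1:19
chr1	402	.	T	C	37.9	.	DP=49	GT:DP	0/0:15	./.:.	0/1:21
chr1	777	.	A	C	52	.	DP=66	GT:DP	0/1:23	0/0:20	0/0:22
chr1	905	.	G	T,C	48.3	.	DP=64	GT:DP	0/1:22	1/2:19	0/0:23
chr2	55	.	T	A	58.1	.	DP=59	GT:DP	0/0:18	0/1:21	1/1:20
chr2	310	.	C	G	45.6	.	DP=62	GT:DP	0/1:20	0/1:19	0/1:22
chr2	511	.	A	T	50	.	DP=57	GT:DP	1/1:26	0/0:18	0/1:21
chr2	980	.	G	C	39.4	.	DP=53	GT:DP	0/0:19	0/1:23	0/0:20
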
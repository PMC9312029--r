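##fileformat=VCFv4.2
##source=popgenscan
##contig=<ID=chr1,length=10000>
##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s01	s02	s03	s04	s05	s06	s07	s08	s09	s10
chr1	100	.	A	G	50	.	DP=60	GT:DP	0/1:20	0/1:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20
chr1	103	.	C	T	50	.	DP=60	GT:DP	0/1:20	0/1:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20
chr1	200	.	G	A	20	.	DP=60	GT:DP	0/1:20	0/1:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20
chr1	300	.	T	C	50	.	DP=60	GT:DP	0/1:20	0/1:20	0/0:4	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20
chr1	400	.	A	C	50	.	DP=100	GT:DP	0/1:20	0/1:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20
chr1	500	.	G	T	50	.	DP=60	GT:DP	0/1:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20
chr1	600	.	C	G	50	.	DP=60	GT:DP	0/1:20	0/1:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20
chr1	700	.	T	A	50	.	DP=60	GT:DP	0/1:20	0/1:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20
chr1	800	.	A	T	50	.	DP=60	GT:DP	0/1:20	0/1:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20
chr1	900	.	G	C	50	.	DP=60	GT:DP	0/1:20	0/1:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20
chr1	1000	.	C	A	50	.	DP=60	GT:DP	0/1:20	0/1:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20
chr1	1100	.	T	G	50	.	DP=60	GT:DP	0/1:20	0/1:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20	0/0:20
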
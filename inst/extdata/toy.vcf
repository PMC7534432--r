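##fileformat=VCFv4.2
##source=handcrafted-toy
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	P1	P2	P3
chr1D	101	s1	A	T	.	PASS	.	GT	0/0	0/1	1/1
chr1D	205	s2	C	G	.	PASS	.	GT	0/0	0/0	0/0
chr1D	310	s3	G	A	.	PASS	.	GT	1/1	./.	0/1
chr1D	400	s4	T	C,G	.	PASS	.	GT	0/1	0/2	1/2
chr2D	50	s5	A	G	.	PASS	.	GT	0/1	0/1	1/1
chr2D	99	s6	T	A	.	PASS	.	GT	1/1	0/0	./.
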
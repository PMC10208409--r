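##fileformat=VCFv4.2
##INFO=<ID=POP_FREQ,Number=1,Type=Float,Description="Population allele frequency">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
##contig=<ID=chr19,length=58617616>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	PT01	PT02
chr19	101	.	A	G	50	PASS	POP_FREQ=0.0001	GT:AD	0/1:20,10	0/0:30,0
chr19	202	.	T	TA,TAA	60	PASS	POP_FREQ=0.002	GT:AD	0/1:15,8,0	0/2:12,0,6
chr19	303	.	GTC	G	40	PASS	POP_FREQ=0.05	GT:AD	0/0:25,0	0/1:18,7
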
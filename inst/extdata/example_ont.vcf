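##fileformat=VCFv4.2
##source=ampliphase-synthetic-cohort
##contig=<ID=chr19>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=PS,Number=1,Type=Integer,Description="Phase set identifier">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S0001
chr19	3750	.	T	C	95.3	.	.	GT:PS:DP	0|1:750:790
chr19	9750	.	A	T	142.0	.	.	GT:PS:DP	0|1:750:184
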
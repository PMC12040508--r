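##fileformat=VCFv4.2
##source=synthetic example records for variant prioritization (crafted, not patient data)
##INFO=<ID=CLNSIG,Number=1,Type=String,Description="ClinVar clinical significance">
##INFO=<ID=REVEL,Number=1,Type=Float,Description="REVEL missense deleteriousness score">
##INFO=<ID=AF,Number=1,Type=Float,Description="Population allele frequency (gnomAD-style)">
##INFO=<ID=IMPACT,Number=1,Type=String,Description="Predicted impact">
##INFO=<ID=Consequence,Number=1,Type=String,Description="Consequence term">
##INFO=<ID=MANE_SELECT,Number=1,Type=Integer,Description="1 if annotated on the MANE Select transcript">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=PS,Number=1,Type=Integer,Description="Phase set">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	SAMPLE1
chr16	89620045	.	G	A	60	PASS	CLNSIG=Pathogenic;REVEL=0.861;AF=0.00001;IMPACT=MODERATE;Consequence=missense_variant;MANE_SELECT=1	GT:PS	1|0:100
chr16	89598310	.	A	AT	60	PASS	CLNSIG=Pathogenic;IMPACT=HIGH;Consequence=frameshift_variant;MANE_SELECT=1	GT:PS	0|1:100
chr3	12345678	.	C	T	60	PASS	REVEL=0.6;IMPACT=MODERATE;Consequence=missense_variant;MANE_SELECT=1	GT	0/1
chr3	12345901	.	G	C	60	PASS	REVEL=0.9;AF=0.2;IMPACT=MODERATE;Consequence=missense_variant;MANE_SELECT=1	GT	0/1
chr5	55555555	.	T	C	60	PASS	CLNSIG=Benign;IMPACT=LOW;Consequence=synonymous_variant;MANE_SELECT=1	GT	0/1
chr7	1000001	.	A	G	60	PASS	REVEL=0.5;IMPACT=MODERATE;Consequence=missense_variant;MANE_SELECT=1	GT	0/1
chr7	1000201	.	A	G	60	PASS	REVEL=0.5;IMPACT=LOW;Consequence=missense_variant;MANE_SELECT=1	GT	0/1
chr9	42424242	.	G	GA	60	PASS	AF=0.0001;IMPACT=HIGH;Consequence=frameshift_variant;MANE_SELECT=1	GT	0/1
chr11	787878	.	C	A	60	PASS	REVEL=0.7;IMPACT=MODERATE;Consequence=missense_variant;MANE_SELECT=0	GT	0/1
chr2	31313131	.	T	A	60	PASS	CLNSIG=Uncertain_significance;IMPACT=MODIFIER;Consequence=intron_variant;MANE_SELECT=1	GT:PS	1|0:200
chr2	31320000	.	G	T	60	PASS	CLNSIG=Conflicting_interpretations_of_pathogenicity;REVEL=0.3;IMPACT=MODERATE;Consequence=missense_variant;MANE_SELECT=1	GT:PS	1|0:200
chr12	9999999	.	C	T	60	PASS	AF=0.05;IMPACT=HIGH;Consequence=stop_gained;MANE_SELECT=1	GT	0/1
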
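##fileformat=VCFv4.2
##source=grsmr synthetic 10-sample fixture
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DS,Number=1,Type=Float,Description="Estimated ALT allele dosage">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S01	S02	S03	S04	S05	S06	S07	S08	S09	S10
4	72618323	rs4588	T	G	.	PASS	.	GT:DS	1/1:2	0/1:1	0/0:0	0/1:1	1/1:2	0/1:1	0/0:0	1/1:2	0/1:1	0/1:1.5
11	14876718	rs116970203	G	A	.	PASS	.	GT:DS	0/0:0	0/0:0	0/1:1	0/0:0	0/0:0	0/0:0	0/1:1	0/0:0	0/0:0	0/0:0
11	14914878	rs10741657	T	C	.	PASS	.	GT:DS	0/1:1	1/1:2	0/1:1	0/0:0	0/1:1	0/1:1	1/1:2	0/0:0	0/1:1	0/1:1
11	71173254	rs4423214	G	A	.	PASS	.	GT:DS	1/1:2	0/1:1	0/1:1	1/1:2	0/1:1	1/1:2	0/1:1	0/1:1	1/1:2	0/1:1
20	52742479	rs6013897	A	T	.	PASS	.	GT:DS	1/1:2	1/1:2	0/1:1	1/1:2	0/1:1	1/1:2	1/1:2	0/1:1	1/1:2	0/1:1
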
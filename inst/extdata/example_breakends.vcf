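##fileformat=VCFv4.2
##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">
##INFO=<ID=READS,Number=.,Type=String,Description="Supporting reads">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chrA	10000	bnd_1	N	N[chrB:40000[	.	PASS	SVTYPE=BND;READS=read01,read02,read03
chrA	10001	bnd_2	N	]chrB:46000]N	.	PASS	SVTYPE=BND;READS=read01,read02
chrA	25000	bnd_3	N	N[chrB:52000[	.	PASS	SVTYPE=BND;READS=read04
chrA	25040	bnd_4	N	]chrB:53000]N	.	PASS	SVTYPE=BND;READS=read05
chrC	5000	bnd_5	N	N]chrB:61500]	.	PASS	SVTYPE=BND;READS=read06,read07
chrC	5010	bnd_6	N	[chrB:60000[N	.	PASS	SVTYPE=BND;READS=read06
chrD	7000	bnd_7	N	N[chrE:90000[	.	PASS	SVTYPE=BND;READS=read08
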
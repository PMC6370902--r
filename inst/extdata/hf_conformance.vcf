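##fileformat=VCFv4.2
##source=depthconcord
##contig=<ID=1,length=1000000>
##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">
##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">
##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand phred score">
##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">
##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Mapping quality rank sum">
##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read position rank sum">
##INFO=<ID=SOR,Number=1,Type=Float,Description="Strand odds ratio">
##INFO=<ID=HaplotypeScore,Number=1,Type=Float,Description="Haplotype count score">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	SAMPLE
1	100	.	A	G	.	.	DP=30;QD=1.5;FS=5.0;MQ=60.0;MQRankSum=0.5;ReadPosRankSum=0.5;SOR=1.0;HaplotypeScore=2.0	GT:DP	0/1:30
1	200	.	C	T	.	.	DP=30;QD=20.0;FS=70.0;MQ=60.0;MQRankSum=0.5;ReadPosRankSum=0.5;SOR=1.0;HaplotypeScore=2.0	GT:DP	0/1:30
1	300	.	G	A	.	.	DP=30;QD=20.0;FS=5.0;MQ=35.0;MQRankSum=0.5;ReadPosRankSum=0.5;SOR=1.0;HaplotypeScore=2.0	GT:DP	0/1:30
1	400	.	T	C	.	.	DP=30;QD=20.0;FS=5.0;MQ=60.0;MQRankSum=-13.0;ReadPosRankSum=0.5;SOR=1.0;HaplotypeScore=2.0	GT:DP	0/1:30
1	500	.	A	C	.	.	DP=30;QD=20.0;FS=5.0;MQ=60.0;MQRankSum=0.5;ReadPosRankSum=-9.0;SOR=1.0;HaplotypeScore=2.0	GT:DP	0/1:30
1	600	.	C	A	.	.	DP=30;QD=20.0;FS=5.0;MQ=60.0;MQRankSum=0.5;ReadPosRankSum=0.5;SOR=1.0;HaplotypeScore=14.0	GT:DP	0/1:30
1	700	.	G	T	.	.	DP=30;QD=20.0;FS=5.0;MQ=60.0;MQRankSum=0.5;ReadPosRankSum=0.5;SOR=3.5;HaplotypeScore=2.0	GT:DP	0/1:30
1	800	.	AT	A	.	.	DP=30;QD=1.0;FS=5.0;MQ=60.0;MQRankSum=0.5;ReadPosRankSum=0.5;SOR=1.0;HaplotypeScore=2.0	GT:DP	0/1:30
1	900	.	C	CA	.	.	DP=30;QD=20.0;FS=250.0;MQ=60.0;MQRankSum=0.5;ReadPosRankSum=0.5;SOR=1.0;HaplotypeScore=2.0	GT:DP	0/1:30
1	1000	.	GTT	G	.	.	DP=30;QD=20.0;FS=5.0;MQ=60.0;MQRankSum=0.5;ReadPosRankSum=-25.0;SOR=1.0;HaplotypeScore=2.0	GT:DP	0/1:30
1	1100	.	T	TGC	.	.	DP=30;QD=20.0;FS=5.0;MQ=60.0;MQRankSum=0.5;ReadPosRankSum=0.5;SOR=12.0;HaplotypeScore=2.0	GT:DP	0/1:30
1	1200	.	A	G	.	.	DP=30;QD=2.0;FS=5.0;MQ=60.0;MQRankSum=0.5;ReadPosRankSum=0.5;SOR=1.0;HaplotypeScore=2.0	GT:DP	0/1:30
1	1300	.	C	T	.	.	DP=30;QD=20.0;FS=60.0;MQ=60.0;MQRankSum=0.5;ReadPosRankSum=0.5;SOR=1.0;HaplotypeScore=2.0	GT:DP	0/1:30
1	1400	.	G	A	.	.	DP=30;QD=20.0;FS=5.0;MQ=60.0;MQRankSum=0.5;ReadPosRankSum=0.5;SOR=3.0;HaplotypeScore=2.0	GT:DP	0/1:30
1	1500	.	T	A	.	.	DP=30;QD=20.0;FS=5.0;MQ=40.0;MQRankSum=0.5;ReadPosRankSum=0.5;SOR=1.0;HaplotypeScore=2.0	GT:DP	0/1:30
1	1600	.	A	T	.	.	DP=30;QD=20.0;FS=5.0;MQ=60.0;MQRankSum=0.5;ReadPosRankSum=0.5;SOR=1.0;HaplotypeScore=13.0	GT:DP	0/1:30
1	1700	.	C	G	.	.	DP=30;QD=20.0;FS=5.0;MQ=60.0;SOR=1.0;HaplotypeScore=2.0	GT:DP	1/1:30
1	1800	.	G	C	.	.	DP=30;QD=20.0;FS=5.0;MQ=60.0;MQRankSum=-12.5;ReadPosRankSum=0.5;SOR=1.0;HaplotypeScore=2.0	GT:DP	0/1:30
1	1900	.	TA	T	.	.	DP=30;QD=20.0;FS=100.0;MQ=60.0;MQRankSum=0.5;ReadPosRankSum=0.5;SOR=1.0;HaplotypeScore=2.0	GT:DP	0/1:30
1	2000	.	A	AGG	.	.	DP=30;QD=20.0;FS=5.0;MQ=60.0;MQRankSum=0.5;ReadPosRankSum=-15.0;SOR=1.0;HaplotypeScore=2.0	GT:DP	0/1:30
1	2100	.	CAA	C	.	.	DP=30;QD=20.0;FS=5.0;MQ=60.0;MQRankSum=0.5;ReadPosRankSum=0.5;SOR=9.0;HaplotypeScore=2.0	GT:DP	0/1:30
1	2200	.	T	G	.	.	DP=30;QD=20.0;FS=5.0;MQ=60.0;MQRankSum=0.5;ReadPosRankSum=0.5;SOR=1.0;HaplotypeScore=2.0	GT:DP	0/1:30
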
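gene	PHLAT	HLA-VBseq	HLA-HD	HISAT-genotype	SNP2HLA
A	100	99.2	95.0	90.1	98.6
C	60.0	90.4	90.0	100	100
B	40.0	98.0	100	89.8	84.8
DRB1	40.0	71.1	100	78.6	45.8
DQA1	100	73.4	100	85.3	91.7
DQB1	100	20.4	90.0	99.4	100
DPA1	NA	NA	100	100	100
DPB1	NA	NA	100	100	98.2
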
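chrom1	breakpoint1	gene1	chrom2	breakpoint2	gene2	reads_label	kind
1	160738159	UHMK1	1	160878664	DDR2	Facing	intrachromosomal
12	70553166	TBC1D15	12	81370954	C12orf26	Same direction – reverse	intrachromosomal
12	77820664	SYT1	12	94015001	FGD6	Same direction – forward	intrachromosomal
12	78116536	SYT1	12	81379417	C12orf26	Opposing	intrachromosomal
12	78600788	PAWR	12	94875477	AMDHD1	Facing	intrachromosomal
12	81369919	C12orf26	12	94014762	FGD6	Opposing	intrachromosomal
12	81371116	C12orf26	12	94875230	AMDHD1	Opposing	intrachromosomal
6	157853571	ZDHHC14	12	78591928	PAWR	Same direction – forward	translocation
11	21368102	NELL1	12	77114108	NAV3	Same direction – reverse	translocation
11	21368605	NELL1	12	78114565	SYT1	Opposing	translocation
11	71472153	LRTOMT	12	81346827	C12orf26	Opposing	translocation
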
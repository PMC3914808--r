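chrom	pos	allele_change	amino_acid_change	gene
2	210491597	G > A	G1704R	UNC80
6	33025040	T > G	K256T	HLA-DMA
10	5129651	A > T	E93V	AKR1C3
11	57183888	C > G	P122A	CLP1
12	79591146	G > A	D125N	PTPRQ
16	69268358	C > T	D253N	MTSS1L
20	49059955	C > T	V110I	KCNG1
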
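marker_id	type	forward	reverse	product_sizes	region	enzyme
pgcpd01	dCAPS	AAATATGACCAACAGTAGTTCGAATCTA	AGCTTATCGGCAGAAACGAA	212/190	rpoC1	XbaI
pgcpd02	dCAPS	ATTTCGGGGACTCACAGAAGTAC	AAAGCAATTTACGCGAAGGA	200/177	rpoC2	ScaI
pgcp139f*r2	InDel	TGTGCGACAAACAAATAAGTCA	CGAAGCGAGTTCCATTTCAT	157/150	rpl32-trnUAG
pgycf1	InDel	GGTATTAGTCTGGATACGGCAAA	TCGAAAAGAAGGGTCACAAGA	729/672/615	ycf1
pgcp097f2*r	InDel	TGGAAAGGCTGTTGTCACTG	TCAGCAACGGGAGATATTCA	390/377/344	rps16-trnUUG
pgcp137	InDel	TCCTGAACCACTAGACGATGG	TTTCGATAACTTCTTGATCCCTCT	514/455	trnUUC-trnGGU
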
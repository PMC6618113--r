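name	position	sequence	orientation	target_group	reference
SSU1ArF	1	TCCGGTTGATCCYGCBRG	fwd	Archaea	this study
SSU280ArR	280	TCAGWNYCCNWCTCSRGG	rev	Archaea	this study
SSU666ArR	666	HGCYTTCGCCACHGGTRG	rev	Archaea	this study
SSU1000ArR	1000	GGCCATGCAMYWCCTCTC	rev	Archaea	this study
SSU520R	520	GCTACGRRYGYTTTARRC	rev	Prokaryotes	this study
SSU470R	470	DCNGCNGGTDTTACCGCG	rev	Prokaryotes	this study
SSU468R	468	GNDCNGCNGGTDTTACCG	rev	Prokaryotes	this study
SSU1492Rngs	1492	CGGNTACCTTGTKACGAC	rev	Prokaryotes	this study
SSU1492Fngs	1492	GTCGTMACAAGGTANCCG	fwd	Prokaryotes	this study
1000R	1000	GGCCATGCACYWCYTCTC	rev	Archaea	Gantner et al. 2011
UA1204R	1204	TTMGGGGCATRCIKACCT	rev	Archaea	Baker et al. 2003
340F	340	CCCTAYGGGGYGCASCAG	fwd	Archaea	Gantner et al. 2011
A571F	571	GCYTAAAGSRNCCGTAGC	fwd	Archaea	Baker et al. 2003
A751F	751	CCGACGGTGAGRGRYGAA	fwd	Archaea	Baker et al. 2003
A519R	519	GGTDTTACCGCGGCKGCTG	rev	Archaea	Wang and Qian 2009
Arch349F	349	GYGCASCAGKCGMGAAW	fwd	Archaea	Takai and Horikoshi 2000
515F	515	GTGCCAGCMGCCGCGGTAA	fwd	Universal	Turner et al. 1999
806rB	806	GGACTACNVGGGTWTCTAAT	rev	Universal	Apprill et al. 2015
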
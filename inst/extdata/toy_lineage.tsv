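taxid	parent	rank	name
1	1	root	Root
2	1	superkingdom	Eukaryota
10	2	phylum	Chlorophyta
11	10	class	Chlorophyceae
12	11	genus	Chlamydomonas
13	12	species	Chlamydomonas_reinhardtii
14	12	species	Chlamydomonas_moewusii
15	12	species	Chlamydomonas_eustigma
20	2	phylum	Ciliophora
21	20	class	Oligohymenophorea
22	21	genus	Paramecium
23	22	species	Paramecium_tetraurelia
30	2	phylum	Bacillariophyta
31	30	genus	Navicula
40	2	phylum	Cryptophyta
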
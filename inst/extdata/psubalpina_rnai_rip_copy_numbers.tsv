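# Copy numbers of RNAi (Argonaute, Dicer, RdRP) and RIP (Dnmt1-family
# cytosine methyltransferase) core genes across nine fungal genomes.
# Species codes: Ps Phialocephala subalpina, Om Oidiodendron maius,
# Ssc Sclerotinia sclerotiorum, Bc Botrytis cinerea, Bg Blumeria graminis,
# Nc Neurospora crassa, Ca Candida albicans, Sc Saccharomyces cerevisiae,
# Sp Schizosaccharomyces pombe. Ambiguous published cells are kept as
# printed (e.g. "2(3)"). `printed_median` is the published median.
mechanism	gene	Ps	Om	Ssc	Bc	Bg	Nc	Ca	Sc	Sp	printed_median
RNAi	Argonaute	4	2	2	3	2(3)	2	1	0	1	2
RNAi	Dicer	4	2	2	2	2	2	0	0	1	2
RNAi	RdRP	5	3	3	3	1	3	0	0	1	3
RIP	Dnmt1	4	3	3	2(3)	0	2	0	0	0	1
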
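# Published classification of transposable-element families in the
# Phialocephala subalpina genome: share of all TEs, cumulative length in
# the genome (kb), and share of the genome.
te_class	family	pct_of_tes	cumulative_kb	pct_genome
ClassI	Gypsy	28.9	1452	2.1
ClassI	Copia	26.1	1308	1.9
ClassI	nonLTR	4.6	229	0.3
ClassII	Tc1_Mariner	8.2	411	0.6
ClassII	Helitron	3.9	194	0.3
ClassII	MITE	1.2	59	0.1
ClassII	hAT	0.6	32	0.0
ClassII	Mutator	0.4	18	0.0
NotClassified	not_classified	26.2	1284	1.8
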
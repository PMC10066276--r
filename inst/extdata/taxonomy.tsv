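child	parent	rank
Mammalia	root	class
Bacteria	root	superkingdom
Pecora	Mammalia	infraorder
Equidae	Mammalia	family
Hominidae	Mammalia	family
Suidae	Mammalia	family
Bovidae	Pecora	family
Cervidae	Pecora	family
Bovinae	Bovidae	subfamily
Caprinae	Bovidae	subfamily
Bos	Bovinae	genus
Bison bison	Bovinae	species
Bos taurus	Bos	species
Bos indicus	Bos	species
Bos grunniens/mutus	Bos	species
Ovis	Caprinae	genus
Capra	Caprinae	genus
Ovis aries	Ovis	species
Capra hircus	Capra	species
Cervus elaphus	Cervidae	species
Equus	Equidae	genus
Equus caballus	Equus	species
Equus asinus	Equus	species
Homo sapiens	Hominidae	species
Sus scrofa	Suidae	species
Streptococcus mitis	Bacteria	species
Streptococcus sanguinis	Bacteria	species
Actinomyces oris	Bacteria	species
Tannerella forsythia	Bacteria	species
Porphyromonas gingivalis	Bacteria	species
Fusobacterium nucleatum	Bacteria	species
Rothia dentocariosa	Bacteria	species
Veillonella parvula	Bacteria	species
Neisseria flavescens	Bacteria	species
Treponema denticola	Bacteria	species
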
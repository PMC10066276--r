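accession	taxon	protein_class	signal_peptide_end
P02754	Bos taurus	whey	16
BLG_BOSIN_SYN	Bos indicus	whey	16
L8J1Z0	Bos grunniens/mutus	whey	16
BLG_BISBI_SYN	Bison bison	whey	16
BLG_OVIAR_SYN	Ovis aries	whey	16
BLG_CAPHI_SYN	Capra hircus	whey	16
BLG_CEREL_SYN	Cervus elaphus	whey	16
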
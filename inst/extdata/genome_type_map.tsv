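taxon	genome_type	host_domain
Caudoviricetes	dsDNA	prokaryotic
Duplodnaviria	dsDNA	unknown
Herviviricetes	dsDNA	eukaryotic
Nucleocytoviricota	dsDNA	eukaryotic
Megaviricetes	dsDNA	eukaryotic
Phycodnaviridae	dsDNA	eukaryotic
Varidnaviria	dsDNA	unknown
Tectiliviricetes	dsDNA	prokaryotic
Corticoviridae	dsDNA	prokaryotic
Ligamenvirales	dsDNA	prokaryotic
Monodnaviria	ssDNA	unknown
Microviridae	ssDNA	prokaryotic
Inoviridae	ssDNA	prokaryotic
Cressdnaviricota	ssDNA	eukaryotic
Parvoviridae	ssDNA	eukaryotic
Riboviria	RNA	unknown
Orthornavirae	RNA	unknown
Lenarviricota	RNA	prokaryotic
Leviviricetes	RNA	prokaryotic
Cystoviridae	RNA	prokaryotic
Kitrinoviricota	RNA	eukaryotic
Pisuviricota	RNA	eukaryotic
Negarnaviricota	RNA	eukaryotic
Duplornaviricota	RNA	eukaryotic
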
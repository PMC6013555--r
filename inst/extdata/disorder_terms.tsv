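disorder	term	name
BIP	GO:0051568	Histone H3-K4 methylation
BIP	GO:0007129	(Chromosomal) synapsis
BIP	GO:0090066	Regulation of anatomical structure size
BIP	GO:0070192	Chromosome organization involved in meiosis
SCZ	GO:0014069	Postsynaptic density
SCZ	GO:0045211	Postsynaptic membrane
SCZ	GO:0043197	Dendritic spine
SCZ	GO:0051568	Histone H3-K4 methylation
SCZ	GO:0033267	Axon part
MDD	GO:0008601	Protein phosphatase type 2A regulator activity
MDD	GO:0034330	Cell junction organization
MDD	GO:0043297	Apical junction assembly
MDD	GO:0045216	Cell-cell junction organization
MDD	GO:0031056	Regulation of histone modification
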
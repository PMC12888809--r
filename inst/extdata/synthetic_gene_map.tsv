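curie	symbol
UniProt:PG001	SYG1
UniProt:PG002	SYG2
UniProt:PG003	SYG3
UniProt:PG004	SYG4
UniProt:PG005	SYG5
UniProt:AMB001	AMBA1
UniProt:AMB001	AMBB1
NCBIGene:7124	TNF
NCBIGene:3569	IL6
NCBIGene:5743	PTGS2
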
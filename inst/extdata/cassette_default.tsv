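role	name	sequence	label
probe	UP1	ccagctgaacggtACGGCA	FAM
probe	UP2	ccagctgaacggtCGTTGC	HEX/JOE/VIC
probe	UP3	ccagctgaacggtAGCCGA	Cy3/TAMRA
probe	UP4	ccagctgaacggtGCGTCA	Cy5/Liz
quencher	Uni-Q	accgttcagctgg	BHQ1/Eclipse
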
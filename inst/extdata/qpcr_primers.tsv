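id	sequence
Scaffold_3-F	GCCACCATGTTCAGATTATTGGAGAGTA
Scaffold_3-R	AATGCCTGACTTATCCATGCCAGGTG
Scaffold_13-F	CGTTTTGTACGTCTGCTGGA
Scaffold_13-R	ACCGGTACCTGTGGTCTAGT
Scaffold_19-F	TGGAGCATGAGTCGAAAAGCA
Scaffold_19-R	TCGCAGAACAGTGTGAACCA
Scaffold_26-F	AGACGGGTCGGGATCTTACA
Scaffold_26-R	TGTTTGAGCATCCCCCAGAC
Scaffold_31-F	CCAAGGCTCAGGAAATAGGGG
Scaffold_31-R	ACCACTGCTTCTCAAAGAGGG
Scaffold_324-F	CAGGTCCCTCTGCGTAACTG
Scaffold_324-R	GACGCCCCAGTCATCATTCA
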
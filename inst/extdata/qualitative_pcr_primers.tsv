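id	sequence
49B1-F	GAGCTTCACACTTGCAGAGGTAAGTCATTTTTGCAGAGAC
49B2-F	GCTTCACACTTGCAGAGGTAAGTCATTTTT
49C+-F	GTTTACAGTCTGATGATGGGACATCATGCTCTGC
49-R	TGTCCAGAGTATAATCGCAGCCTTTGCGGT
80B-F	GAGGCATTACATCGGTCTTTCCATCA
80C+-F	GGTGAGCAGCAGGATTTTGAATTGAATGCG
80-R	CCTGATTGAGTGCTTCTCACAC
182B1-F	GGGTGTGTTTGGTTGTGGTTTGACAAGGAGTG
182B2-F	GGAGTGAATTGTGATGGT
182B3-F	GGTTTGACAAGGAGTGAATTGTGATGGTTAGATC
182B4-F	GAGTGAATTGTGATGGTTAGATCACTAGGTAT
182C+-F	AGAATGGTCCAAGGAAGG
182-R	CCATCAGAACCAGCATTAA
207B-F	GAGACACTTCTTGGAGAAAATGAAATGCCCAC
207C+-F	ACCAGGCCAGGAGACGACTGAAGAACT
207-R	GACCTGCAGAAATGTGAACATGGTTGCAGTTTACAA
323B-F	GGGGGTGTTTTGCTTTTGGTTTTCCTACATTAGTTA
323C+-F	GTATAAGCCATCTCTGTCATCTAAGGTACA
323-R	GACACAGTACAGCTGACACAGACGAAGCAACAG
764B-F	CCTGAGATGGTCCGATTGGGCTGGTAA
764C+-F	GGTGAAGCATCAAAGAGCTCTCTGAGTCT
764-R	GGAGACAAGGAGATGCGTGTTGGTGAAGTCCTAA
1100B-F	GGGTGTGTGGAGATGTACATCAGCACACATGTT
1100C+-F	CACTGAGACGGCATTGGCATGAGAAA
1100-R	AGCATGGTGGCAGAGGTCTTTA
1987B-F	CCCTCCTGTTATTCATTCCCTA
1987C+-F	TACTTTGCTGTGTGTTTTGCCTGTC
1987-R	AAGTGTGGCTGTGTGCAGGCAGGAAT
2519B-F	GCAGGATTCAGGAGTGAAGCATCTGTGTGA
2519C+-F	CACTAAACTGCAGACATCAGGCTG
2519-R	CATTGTTCTGCTGCAGTCAATGGAC
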
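Scaffold_3	9112721	9126380	region_scaffold_3	0
Scaffold_13	5682225	5684956	region_scaffold_13	0
Scaffold_19	960417	963148	region_scaffold_19	0
Scaffold_26	1707513	1710244	region_scaffold_26	0
Scaffold_31	5673821	5680650	region_scaffold_31	0
Scaffold_324	77097	77779	region_scaffold_324	0
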
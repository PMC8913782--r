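tissueType	cellName	geneSymbolmore1	geneSymbolmore2
Immune system	B cell	CD79A,CD79B,CD19,MS4A1	
Immune system	Plasma cell	SDC1,PRDM1	CD19,MS4A1
Immune system	T cell	CD3D,CD3E	
Liver	Hepatocyte	ALB,TTR	
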
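ncbi-gene	29843	9606	SENP1	SuPr-2|sentrin specific peptidase 1
ncbi-gene	23410	9606	SIRT3	SIR2L3|sirtuin 3
ncbi-gene	64213	10090	Sirt3	mouse sirtuin 3
ncbi-gene	6648	9606	SOD2	MnSOD|superoxide dismutase 2
ncbi-gene	7157	9606	TP53	p53|tumor protein p53
ncbi-gene	22059	10090	Trp53	p53|transformation related protein 53
chebi	15422		ATP	adenosine triphosphate
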
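snp_id	subtype	gene	allele1	allele2	ctrl_11	ctrl_12	ctrl_22	case_11	case_12	case_22
rs227849	OMA	RUNX2/SUPT3H/CDC5L	A	G	39	39	17	7	27	16
rs4703908	OMA	ZNF366	C	G	64	30	1	24	21	5
rs2479037	OMA	VTI1A	C	T	5	25	160	0	3	63
rs966674	OMA	-	C	G	169	22	1	50	17	3
rs4703908	DIG	ZNF366	C	G	64	30	1	15	22	0
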
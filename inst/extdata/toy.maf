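#version 2.4
Hugo_Symbol	Chromosome	Start_Position	Reference_Allele	Tumor_Seq_Allele2	Variant_Type	Tumor_Sample_Barcode	t_alt_count	t_depth	ExAC_AF
TP53	17	7577120	C	T	SNP	PT01	12	60	0.0001
KRAS	12	25398284	C	A	SNP	PT01	8	40
EGFR	7	55242465	-	GGAATTAAGAGAAGC	INS	PT02	6	30	0.0002
BRAF	7	140453136	A	-	DEL	PT02	9	45	0.0003
PIK3CA	3	178936091	G	A	SNP	PT02	5	50	0.02
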
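name	section	value_kind	context_axis	min	max	weight
MAF	SNPs and Genes	continuous		0	0.5	0.3133
Localization	SNPs and Genes	categorical			 	0.7052
Essential Genes	SNPs and Genes	binary				0.2665
Phylo	SNPs and Genes	continuous		0	1	0.5797
Lamina associated domains	SNPs and Genes	binary				0.2444
Open Chromatin	Epigenetics and transcription regulations	binary	tissue			0.1596
Chromatin Structure	Epigenetics and transcription regulations	binary	tissue			0.7525
Methylation (seq regions)	Epigenetics and transcription regulations	binary	tissue			0.4009
Methylation	Epigenetics and transcription regulations	binary	tissue			0.3743
CpG Island	Epigenetics and transcription regulations	binary				0.8992
DNase clusters	Epigenetics and transcription regulations	binary	tissue			0.9558
TSS (eponine)	Epigenetics and transcription regulations	binary				0.3705
CpG islands, promoters, first exons	Epigenetics and transcription regulations	binary				0.9665
FOX2 CLIP-seq	Epigenetics and transcription regulations	binary				0.5608
TAF1 binding sites	Epigenetics and transcription regulations	binary				0.2468
Intergenic regulatory elements	Epigenetics and transcription regulations	binary				0.4006
TSS (SwitchGear)	Epigenetics and transcription regulations	binary				0.6773
Regulatory regions (OregAnno)	Epigenetics and transcription regulations	binary				0.8818
TFBS (TRANSFAC)	Epigenetics and transcription regulations	binary				0.8243
TXN factor ChIP-Seq	Epigenetics and transcription regulations	binary	cell_line			0.4477
Enhancers (VISTA)	Epigenetics and transcription regulations	binary				0.9571
Alternative Splicing	Translation regulations	binary				0.7032
miRNA binding regions	Translation regulations	binary				0.8358
Hub protein	Proteins	binary				0.5796
Protein Domain	Proteins	binary				0.6316
PolyPhen	Proteins	continuous		0	1	0.5678
SNPs 3D	Proteins	binary				0.5977
LS-SNP	Proteins	binary				0.3158
Protein Interactions	Proteins	binary				0.3728
PTM	Proteins	binary				0.5399
Pathologies OMIM	Disease	binary				0.2904
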
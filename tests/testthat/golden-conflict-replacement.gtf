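# GTF written by genemerge
chr1	genemerge	exon	101	200	0.75	+	.	gene_id "GM_00001"; transcript_id "GM_00001"; support_class "SUPPORTED";
chr1	genemerge	exon	501	600	0.75	+	.	gene_id "GM_00001"; transcript_id "GM_00001"; support_class "SUPPORTED";
chr1	genemerge	exon	901	1000	0.75	+	.	gene_id "GM_00001"; transcript_id "GM_00001"; support_class "SUPPORTED";
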
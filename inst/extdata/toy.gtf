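chr1	toy	exon	101	300	.	+	.	gene_id "geneA"; transcript_id "geneA.t1";
chr1	toy	exon	501	700	.	+	.	gene_id "geneA"; transcript_id "geneA.t1";
chr1	toy	CDS	151	300	.	+	.	gene_id "geneA"; transcript_id "geneA.t1";
chr1	toy	CDS	501	600	.	+	.	gene_id "geneA"; transcript_id "geneA.t1";
chr1	toy	exon	1001	1400	.	-	.	gene_id "geneB"; transcript_id "geneB.t1";
chr1	toy	CDS	1101	1350	.	-	.	gene_id "geneB"; transcript_id "geneB.t1";
chr1	toy	exon	2001	2200	.	+	.	gene_id "geneC"; transcript_id "geneC.t1";
chr1	toy	exon	2101	2400	.	+	.	gene_id "geneC"; transcript_id "geneC.t2";
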
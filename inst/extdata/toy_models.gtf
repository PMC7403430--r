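10	toy	exon	100	199	.	+	.	gene_id "TOYG1"; gene_name "TOY1"; transcript_id "TOYT1"; gene_biotype "protein_coding";
10	toy	exon	300	499	.	+	.	gene_id "TOYG1"; gene_name "TOY1"; transcript_id "TOYT1"; gene_biotype "protein_coding";
10	toy	CDS	312	450	.	+	.	gene_id "TOYG1"; gene_name "TOY1"; transcript_id "TOYT1"; gene_biotype "protein_coding";
11	toy	exon	100	199	.	-	.	gene_id "TOYG2"; gene_name "TOY2"; transcript_id "TOYT2"; gene_biotype "protein_coding";
11	toy	exon	300	499	.	-	.	gene_id "TOYG2"; gene_name "TOY2"; transcript_id "TOYT2"; gene_biotype "protein_coding";
11	toy	CDS	150	420	.	-	.	gene_id "TOYG2"; gene_name "TOY2"; transcript_id "TOYT2"; gene_biotype "protein_coding";
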
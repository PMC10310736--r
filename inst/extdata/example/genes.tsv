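gene_id	symbol	biotype	transcript_id	chrom	start	end	exon_starts	exon_ends	cds_side
g0001	GENE0001	protein_coding	g0001.t1	chr1	100001	140000	100001,120000,135000	110000,125000,140000	left
g0001	GENE0001	protein_coding	g0001.t2	chr1	100001	128000	100001,120000	110000,128000	left
g0002	GENE0002	protein_coding	g0002.t1	chr1	200001	230000	200001,225000	210000,230000	right
g0003	GENE0003	other	g0003.t1	chr2	50001	60000	50001	60000	left
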
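chrom	start	end	cnv_type	frequency	coordinate_flavor	source
chr1	95001	160000	loss	0.02	outer	DGV_GOLD
chr1	100001	150000	loss	0.02	inner	DGV_GOLD
chr1	95001	160000	loss	0.02	plain	DGV
chr2	500001	700000	gain	0.004	plain	GnomAD
chr2	800001	900000	loss	0.001	plain	GnomAD
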
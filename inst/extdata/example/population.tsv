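chrom	start	end	cnv_type	allele_frequency
chr1	90001	170000	loss	0.03
chr2	400001	450000	gain	0.002
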
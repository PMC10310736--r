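symbol	target_kind	chrom	start	end	hi_score	ts_score
GENE0001	gene	chr1	100001	140000	3	NA
GENE0002	gene	chr1	200001	230000	2	NA
REGION01	region	chr2	1000001	1200000	NA	3
REGION02	region	chr2	2000001	2100000	40	NA
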
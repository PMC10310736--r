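chrom	start	end	element_class
chr1	300001	300800	enhancer
chr2	1500001	1501200	known_functional_element
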
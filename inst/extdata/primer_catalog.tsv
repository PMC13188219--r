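name	fwd_primer	rev_primer	window_start	window_end	start_region	end_region
27F-338R	AGAGTTTGATCMTGGCTCAG	TGCTGCCTCCCGTAGGAGT	27	336	V1	V2
341F-805R	CCTACGGGNGGCWGCAG	GACTACHVGGGTATCTAATCC	357	783	V3	V4
515F-806R	GTGYCAGCMGCCGCGGTAA	GGACTACNVGGGTWTCTAAT	532	785	V4	V4
515F-926R	GTGYCAGCMGCCGCGGTAA	CCGYCAATTYMTTTRAGTTT	532	905	V4	V5
341F-926R	CCTACGGGNGGCWGCAG	CCGYCAATTYMTTTRAGTTT	357	905	V3	V5
1115F-1492R	CAACGAGCGCAACCC	TACGGYTACCTTGTTACGACTT	1115	1467	V7	V9
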
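# synthetic hg19 gene coordinates; BED 0-based starts
chr8	110052908	110184293	TRHR	0	+
chr3	157814798	157985245	SHOX2	0	+
chr3	157987244	158157690	RSRC1	0	+
chr3	158159689	158330136	MLF1	0	+
chr2	38791326	38898563	SOS1	0	+
chr2	38900562	39007800	MAP4K3	0	+
chr2	39009799	39117037	CDKL4	0	+
chr2	39119036	39226273	HNRPLL	0	+
chr2	39228272	39335509	SRSF7	0	+
chr2	39337508	39444746	DHX57	0	+
chr2	39446745	39553983	MORN2	0	+
chr2	39555982	39663219	ARHGEF33	0	+
chr18	29688012	29804315	RNF138	0	+
chr18	29806314	29922616	WBP11P1	0	+
chr18	29924615	30040918	FAM59A	0	+
chr18	30042917	30159219	KLHL14	0	+
chr18	30161218	30277521	MEP1B	0	+
chr7	145813452	148118091	CNTNAP2	0	+
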
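locus	chrom	start_bp	end_bp	printed_length_kb	genes	patients
8q23.1	chr8	110051909	110185293	820	TRHR	F4-015,F6-024,F7-029,F9-038,F40-186
3q25.32	chr3	157813799	158331136	517	MLF1,RSRC1,SHOX2	F4-015,F6-024,F20-093,F27-122,F28-127,F36-169
2p22.1	chr2	38790327	39664219	873	SOS1,MAP4K3,CDKL4,HNRPLL,SRSF7,DHX57,MORN2,ARHGEF33	F1-001,F3-010,F6-024,F18-083,F19-088,F19-089,F29-133
18q12.1	chr18	29687013	30278521	591	RNF138,WBP11P1,FAM59A,KLHL14,MEP1B	F3-010,F4-015,F20-093,F22-101,F28-127,F35-164,F36-169
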
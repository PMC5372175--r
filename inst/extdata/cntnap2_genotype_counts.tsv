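group	nNN	nNV	nVV
patients	14	15	8
parents	7	19	10
siblings	11	10	12
family_cohort	32	44	30
controls	34	50	16
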
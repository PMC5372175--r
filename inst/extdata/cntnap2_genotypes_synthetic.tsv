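sample	genotype	group
F1-001	NN	patients
F2-005	NN	patients
F3-010	NN	patients
F4-015	NN	patients
F5-020	NN	patients
F6-024	NN	patients
F7-029	NN	patients
F8-034	NN	patients
F9-038	NN	patients
F11-048	NN	patients
F15-070	NN	patients
F17-080	NN	patients
F18-083	NN	patients
F19-088	NN	patients
F19-089	NV	patients
F20-093	NV	patients
F22-101	NV	patients
F24-108	NV	patients
F27-122	NV	patients
F28-127	NV	patients
F29-133	NV	patients
F31-145	NV	patients
F32-148	NV	patients
F33-152	NV	patients
F34-158	NV	patients
F35-164	NV	patients
F36-169	NV	patients
F37-172	NV	patients
F38-176	NV	patients
F39-180	VV	patients
F40-186	VV	patients
F41-190	VV	patients
F42-194	VV	patients
F43-197	VV	patients
F44-201	VV	patients
F45-205	VV	patients
F46-211	VV	patients
F1-PAR	NN	parents
F2-PAR	NN	parents
F3-PAR	NN	parents
F4-PAR	NN	parents
F5-PAR	NN	parents
F6-PAR	NN	parents
F7-PAR	NN	parents
F8-PAR	NV	parents
F9-PAR	NV	parents
F11-PAR	NV	parents
F15-PAR	NV	parents
F17-PAR	NV	parents
F18-PAR	NV	parents
F19-PAR	NV	parents
F20-PAR	NV	parents
F22-PAR	NV	parents
F24-PAR	NV	parents
F27-PAR	NV	parents
F28-PAR	NV	parents
F29-PAR	NV	parents
F31-PAR	NV	parents
F32-PAR	NV	parents
F33-PAR	NV	parents
F34-PAR	NV	parents
F35-PAR	NV	parents
F36-PAR	NV	parents
F37-PAR	VV	parents
F38-PAR	VV	parents
F39-PAR	VV	parents
F40-PAR	VV	parents
F41-PAR	VV	parents
F42-PAR	VV	parents
F43-PAR	VV	parents
F44-PAR	VV	parents
F45-PAR	VV	parents
F46-PAR	VV	parents
F1-SIB	NN	siblings
F2-SIB	NN	siblings
F3-SIB	NN	siblings
F4-SIB	NN	siblings
F5-SIB	NN	siblings
F6-SIB	NN	siblings
F7-SIB	NN	siblings
F8-SIB	NN	siblings
F9-SIB	NN	siblings
F11-SIB	NN	siblings
F15-SIB	NN	siblings
F17-SIB	NV	siblings
F18-SIB	NV	siblings
F20-SIB	NV	siblings
F22-SIB	NV	siblings
F24-SIB	NV	siblings
F27-SIB	NV	siblings
F28-SIB	NV	siblings
F29-SIB	NV	siblings
F31-SIB	NV	siblings
F32-SIB	NV	siblings
F33-SIB	VV	siblings
F34-SIB	VV	siblings
F35-SIB	VV	siblings
F36-SIB	VV	siblings
F37-SIB	VV	siblings
F38-SIB	VV	siblings
F39-SIB	VV	siblings
F40-SIB	VV	siblings
F41-SIB	VV	siblings
F42-SIB	VV	siblings
F43-SIB	VV	siblings
F44-SIB	VV	siblings
CTRL-001	NN	controls
CTRL-002	NN	controls
CTRL-003	NN	controls
CTRL-004	NN	controls
CTRL-005	NN	controls
CTRL-006	NN	controls
CTRL-007	NN	controls
CTRL-008	NN	controls
CTRL-009	NN	controls
CTRL-010	NN	controls
CTRL-011	NN	controls
CTRL-012	NN	controls
CTRL-013	NN	controls
CTRL-014	NN	controls
CTRL-015	NN	controls
CTRL-016	NN	controls
CTRL-017	NN	controls
CTRL-018	NN	controls
CTRL-019	NN	controls
CTRL-020	NN	controls
CTRL-021	NN	controls
CTRL-022	NN	controls
CTRL-023	NN	controls
CTRL-024	NN	controls
CTRL-025	NN	controls
CTRL-026	NN	controls
CTRL-027	NN	controls
CTRL-028	NN	controls
CTRL-029	NN	controls
CTRL-030	NN	controls
CTRL-031	NN	controls
CTRL-032	NN	controls
CTRL-033	NN	controls
CTRL-034	NN	controls
CTRL-035	NV	controls
CTRL-036	NV	controls
CTRL-037	NV	controls
CTRL-038	NV	controls
CTRL-039	NV	controls
CTRL-040	NV	controls
CTRL-041	NV	controls
CTRL-042	NV	controls
CTRL-043	NV	controls
CTRL-044	NV	controls
CTRL-045	NV	controls
CTRL-046	NV	controls
CTRL-047	NV	controls
CTRL-048	NV	controls
CTRL-049	NV	controls
CTRL-050	NV	controls
CTRL-051	NV	controls
CTRL-052	NV	controls
CTRL-053	NV	controls
CTRL-054	NV	controls
CTRL-055	NV	controls
CTRL-056	NV	controls
CTRL-057	NV	controls
CTRL-058	NV	controls
CTRL-059	NV	controls
CTRL-060	NV	controls
CTRL-061	NV	controls
CTRL-062	NV	controls
CTRL-063	NV	controls
CTRL-064	NV	controls
CTRL-065	NV	controls
CTRL-066	NV	controls
CTRL-067	NV	controls
CTRL-068	NV	controls
CTRL-069	NV	controls
CTRL-070	NV	controls
CTRL-071	NV	controls
CTRL-072	NV	controls
CTRL-073	NV	controls
CTRL-074	NV	controls
CTRL-075	NV	controls
CTRL-076	NV	controls
CTRL-077	NV	controls
CTRL-078	NV	controls
CTRL-079	NV	controls
CTRL-080	NV	controls
CTRL-081	NV	controls
CTRL-082	NV	controls
CTRL-083	NV	controls
CTRL-084	NV	controls
CTRL-085	VV	controls
CTRL-086	VV	controls
CTRL-087	VV	controls
CTRL-088	VV	controls
CTRL-089	VV	controls
CTRL-090	VV	controls
CTRL-091	VV	controls
CTRL-092	VV	controls
CTRL-093	VV	controls
CTRL-094	VV	controls
CTRL-095	VV	controls
CTRL-096	VV	controls
CTRL-097	VV	controls
CTRL-098	VV	controls
CTRL-099	VV	controls
CTRL-100	VV	controls
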
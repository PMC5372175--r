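F1	F1-PAR	0	0	1	1
F1	F1-001	F1-PAR	0	1	2
F1	F1-SIB	F1-PAR	0	2	1
F2	F2-PAR	0	0	1	1
F2	F2-005	F2-PAR	0	1	2
F2	F2-SIB	F2-PAR	0	2	1
F3	F3-PAR	0	0	1	1
F3	F3-010	F3-PAR	0	1	2
F3	F3-SIB	F3-PAR	0	2	1
F4	F4-PAR	0	0	1	1
F4	F4-015	F4-PAR	0	1	2
F4	F4-SIB	F4-PAR	0	2	1
F5	F5-PAR	0	0	1	1
F5	F5-020	F5-PAR	0	1	2
F5	F5-SIB	F5-PAR	0	2	1
F6	F6-PAR	0	0	1	1
F6	F6-024	F6-PAR	0	1	2
F6	F6-SIB	F6-PAR	0	2	1
F7	F7-PAR	0	0	1	1
F7	F7-029	F7-PAR	0	1	2
F7	F7-SIB	F7-PAR	0	2	1
F8	F8-PAR	0	0	1	1
F8	F8-034	F8-PAR	0	1	2
F8	F8-SIB	F8-PAR	0	2	1
F9	F9-PAR	0	0	1	1
F9	F9-038	F9-PAR	0	1	2
F9	F9-SIB	F9-PAR	0	2	1
F11	F11-PAR	0	0	1	1
F11	F11-048	F11-PAR	0	1	2
F11	F11-SIB	F11-PAR	0	1	1
F15	F15-PAR	0	0	1	1
F15	F15-070	F15-PAR	0	1	2
F15	F15-SIB	F15-PAR	0	1	1
F17	F17-PAR	0	0	1	1
F17	F17-080	F17-PAR	0	1	2
F17	F17-SIB	F17-PAR	0	1	1
F18	F18-PAR	0	0	1	1
F18	F18-083	F18-PAR	0	1	2
F18	F18-SIB	F18-PAR	0	1	1
F19	F19-PAR	0	0	1	1
F19	F19-088	F19-PAR	0	1	2
F19	F19-089	F19-PAR	0	1	2
F20	F20-PAR	0	0	1	1
F20	F20-093	F20-PAR	0	1	2
F20	F20-SIB	F20-PAR	0	1	1
F22	F22-PAR	0	0	1	1
F22	F22-101	F22-PAR	0	1	2
F22	F22-SIB	F22-PAR	0	1	1
F24	F24-PAR	0	0	1	1
F24	F24-108	F24-PAR	0	1	2
F24	F24-SIB	F24-PAR	0	1	1
F27	F27-PAR	0	0	1	1
F27	F27-122	F27-PAR	0	1	2
F27	F27-SIB	F27-PAR	0	1	1
F28	F28-PAR	0	0	1	1
F28	F28-127	F28-PAR	0	1	2
F28	F28-SIB	F28-PAR	0	1	1
F29	F29-PAR	0	0	1	1
F29	F29-133	F29-PAR	0	1	2
F29	F29-SIB	F29-PAR	0	1	1
F31	F31-PAR	0	0	1	1
F31	F31-145	F31-PAR	0	1	2
F31	F31-SIB	F31-PAR	0	1	1
F32	F32-PAR	0	0	1	1
F32	F32-148	F32-PAR	0	1	2
F32	F32-SIB	F32-PAR	0	1	1
F33	F33-PAR	0	0	1	1
F33	F33-152	F33-PAR	0	1	2
F33	F33-SIB	F33-PAR	0	1	1
F34	F34-PAR	0	0	1	1
F34	F34-158	F34-PAR	0	1	2
F34	F34-SIB	F34-PAR	0	1	1
F35	F35-PAR	0	0	1	1
F35	F35-164	F35-PAR	0	2	2
F35	F35-SIB	F35-PAR	0	1	1
F36	F36-PAR	0	0	1	1
F36	F36-169	F36-PAR	0	1	2
F36	F36-SIB	F36-PAR	0	1	1
F37	F37-PAR	0	0	1	1
F37	F37-172	F37-PAR	0	1	2
F37	F37-SIB	F37-PAR	0	1	1
F38	F38-PAR	0	0	1	1
F38	F38-176	F38-PAR	0	1	2
F38	F38-SIB	F38-PAR	0	1	1
F39	F39-PAR	0	0	1	1
F39	F39-180	F39-PAR	0	1	2
F39	F39-SIB	F39-PAR	0	1	1
F40	F40-PAR	0	0	1	1
F40	F40-186	F40-PAR	0	1	2
F40	F40-SIB	F40-PAR	0	1	1
F41	F41-PAR	0	0	1	1
F41	F41-190	F41-PAR	0	1	2
F41	F41-SIB	F41-PAR	0	1	1
F42	F42-PAR	0	0	1	1
F42	F42-194	F42-PAR	0	1	2
F42	F42-SIB	F42-PAR	0	1	1
F43	F43-PAR	0	0	1	1
F43	F43-197	F43-PAR	0	1	2
F43	F43-SIB	F43-PAR	0	1	1
F44	F44-PAR	0	0	1	1
F44	F44-201	F44-PAR	0	1	2
F44	F44-SIB	F44-PAR	0	1	1
F45	F45-PAR	0	0	1	1
F45	F45-205	F45-PAR	0	1	2
F46	F46-PAR	0	0	1	1
F46	F46-211	F46-PAR	0	2	2
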
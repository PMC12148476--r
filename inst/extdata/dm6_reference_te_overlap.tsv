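island_type	type_label	total_count	overlapping_pairs	pct
CpG	Rt1a	30	48	160
CpG	G6	15	21	140
CpG	Rt1b	60	63	105
CpG	opus	44	40	91
CpG	Max	24	21	88
CpG	R1A1	31	25	81
CpG	GATE	19	15	79
CpG	gypsy8	56	42	75
CpA	roo	144	388	269
CpA	gypsy2	16	36	225
CpA	opus	44	68	155
CpA	springer	22	34	155
CpA	flea	29	43	148
CpA	Max	24	32	133
CpA	gypsy3	15	20	133
CpA	GATE	19	25	132
CpT	Transpac	12	27	225
CpT	Stalker2	17	37	218
CpT	opus	44	88	200
CpT	Tirant	25	45	180
CpT	17.6	29	50	172
CpT	HMS-Beagle	24	41	171
CpT	gypsy5	10	17	170
CpT	297	89	146	164
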
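sample_id	caller	fusions_overall	tp	published_tp_rate_percent
T1	ericscript	207	3	1.45
T2	ericscript	275	0	0
T3	ericscript	180	0	0
T4	ericscript	188	1	0.53
T5	ericscript	211	2	0.95
T6	ericscript	165	0	0
T7	ericscript	182	0	0
T8	ericscript	133	0	0
T9	ericscript	336	0	0
T10	ericscript	189	4	2.12
T1	jaffa	37	5	13.51
T2	jaffa	22	1	4.55
T3	jaffa	13	0	0
T4	jaffa	20	0	0
T5	jaffa	8	2	25.00
T6	jaffa	16	1	6.25
T7	jaffa	15	3	20.00
T8	jaffa	12	0	0
T9	jaffa	30	1	3.33
T10	jaffa	29	6	20.69
T1	fusioncatcher	48	4	8.33
T2	fusioncatcher	19	2	10.53
T3	fusioncatcher	18	0	0
T4	fusioncatcher	7	1	14.29
T5	fusioncatcher	10	1	10.00
T6	fusioncatcher	14	1	7.14
T7	fusioncatcher	31	4	12.90
T8	fusioncatcher	39	1	2.56
T9	fusioncatcher	29	1	3.45
T10	fusioncatcher	53	7	13.21
T1	meta-caller	9	3	33.33
T2	meta-caller	2	1	50.00
T3	meta-caller	1	0	0
T4	meta-caller	2	1	50.00
T5	meta-caller	3	2	66.67
T6	meta-caller	1	1	100.00
T7	meta-caller	6	3	50.00
T8	meta-caller	1	0	0
T9	meta-caller	4	1	25.00
T10	meta-caller	11	7	63.64
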
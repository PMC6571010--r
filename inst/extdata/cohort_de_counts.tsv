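sample	pcomp_up	pcomp_down	pcomp_total	array_up	array_down	array_total	overlap_up	overlap_down	overlap_total
T1	1534	552	2086	707	399	1106	351	29	380
T2	539	66	605	253	83	336	54	1	55
T3	314	82	396	124	92	216	22	3	25
T4	1768	657	2425	482	154	636	207	66	273
T5	1572	355	1927	567	77	644	78	21	99
T6	1346	258	1604	644	134	778	178	38	216
T7	1865	245	2110	423	186	609	164	15	179
T8	1855	419	2274	1446	428	1874	682	55	737
T9	544	96	640	124	92	216	27	3	30
T10	968	165	1133	213	50	263	45	5	50
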
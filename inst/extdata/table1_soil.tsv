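depth	treatment	variable	mean	sd
0-20	CK	water_content	16	1.4
0-20	Y5	water_content	15.9	0.8
0-20	Y10	water_content	17.1	1.8
0-20	Y15	water_content	17.2	1.9
0-20	Overall	water_content	16.6	1.5
0-20	CK	EC	88.9	10.9
0-20	Y5	EC	101.6	2.3
0-20	Y10	EC	104.3	13.9
0-20	Y15	EC	116.3	9.4
0-20	Overall	EC	102.8	13.3
0-20	CK	SOC	18.9	0.3
0-20	Y5	SOC	15.2	0.1
0-20	Y10	SOC	13.9	0.6
0-20	Y15	SOC	13.9	0.3
0-20	Overall	SOC	15.5	2.1
0-20	CK	TN	1.3	0.1
0-20	Y5	TN	1	0.2
0-20	Y10	TN	0.9	0.1
0-20	Y15	TN	0.9	0
0-20	Overall	TN	1	0.2
0-20	CK	NO3_N	55.5	12.1
0-20	Y5	NO3_N	51.5	0.9
0-20	Y10	NO3_N	50	4.1
0-20	Y15	NO3_N	43.7	0.4
0-20	Overall	NO3_N	50.2	7
0-20	CK	NH4_N	6.1	0.2
0-20	Y5	NH4_N	5	0.4
0-20	Y10	NH4_N	3.7	1.4
0-20	Y15	NH4_N	3.3	0.4
0-20	Overall	NH4_N	4.5	1.3
0-20	CK	TP	0.9	0
0-20	Y5	TP	0.7	0
0-20	Y10	TP	1.2	0.1
0-20	Y15	TP	1.5	0.1
0-20	Overall	TP	1.1	0.3
0-20	CK	AP	9	1.3
0-20	Y5	AP	12.7	0.9
0-20	Y10	AP	13.6	0.8
0-20	Y15	AP	16.3	0.7
0-20	Overall	AP	12.9	2.8
20-40	CK	water_content	14.7	2.7
20-40	Y5	water_content	16.8	0.6
20-40	Y10	water_content	21.4	1.3
20-40	Y15	water_content	21.2	1.9
20-40	Overall	water_content	18.5	3.4
20-40	CK	EC	94.6	5
20-40	Y5	EC	104.6	1.9
20-40	Y10	EC	107.9	17.6
20-40	Y15	EC	108.3	12.3
20-40	Overall	EC	103.9	11
20-40	CK	SOC	14.2	1
20-40	Y5	SOC	13.9	0.3
20-40	Y10	SOC	12.6	1.3
20-40	Y15	SOC	12.4	0.5
20-40	Overall	SOC	13.3	1.1
20-40	CK	TN	0.9	0
20-40	Y5	TN	0.9	0.1
20-40	Y10	TN	0.8	0.1
20-40	Y15	TN	0.7	0.2
20-40	Overall	TN	0.8	0.1
20-40	CK	NO3_N	54	2.7
20-40	Y5	NO3_N	43.4	5.7
20-40	Y10	NO3_N	42.3	1.6
20-40	Y15	NO3_N	33.7	0.5
20-40	Overall	NO3_N	43.4	8
20-40	CK	NH4_N	5.9	0.7
20-40	Y5	NH4_N	4	0.8
20-40	Y10	NH4_N	3.5	0.4
20-40	Y15	NH4_N	2.8	0.4
20-40	Overall	NH4_N	4.1	1.3
20-40	CK	TP	0.7	0
20-40	Y5	TP	0.5	0
20-40	Y10	TP	0.9	0
20-40	Y15	TP	0.9	0
20-40	Overall	TP	0.7	0.2
20-40	CK	AP	7.7	1.2
20-40	Y5	AP	5.7	0.4
20-40	Y10	AP	12.8	3
20-40	Y15	AP	11.4	1.2
20-40	Overall	AP	9.4	3.3
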
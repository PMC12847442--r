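depth	treatment	variable	mean	sd
0-20	CK	BG	265.5	15.1
0-20	Y5	BG	233.9	9.3
0-20	Y10	BG	210.6	8.8
0-20	Y15	BG	130.1	7.2
0-20	Overall	BG	210	57.8
0-20	CK	CBH	29.5	1.5
0-20	Y5	CBH	23.9	2.5
0-20	Y10	CBH	26.3	1.1
0-20	Y15	CBH	15.3	2.5
0-20	Overall	CBH	23.8	6.1
0-20	CK	NAG	35.2	1
0-20	Y5	NAG	27.6	2
0-20	Y10	NAG	25.5	6.8
0-20	Y15	NAG	13.1	1.2
0-20	Overall	NAG	25.4	9.2
0-20	CK	LAP	147.7	5.3
0-20	Y5	LAP	133.6	2.6
0-20	Y10	LAP	128.6	12.6
0-20	Y15	LAP	88.2	2.6
0-20	Overall	LAP	124.5	25.5
0-20	CK	ALP	287.5	14.4
0-20	Y5	ALP	344.9	10.2
0-20	Y10	ALP	333.5	8.5
0-20	Y15	ALP	365.9	3.4
0-20	Overall	ALP	333	33.1
0-20	CK	c_to_n	1.6	0.1
0-20	Y5	c_to_n	1.6	0.1
0-20	Y10	c_to_n	1.5	0.2
0-20	Y15	c_to_n	1.4	0.1
0-20	Overall	c_to_n	1.5	0.1
0-20	CK	c_to_p	1	0.1
0-20	Y5	c_to_p	0.7	0
0-20	Y10	c_to_p	0.7	0
0-20	Y15	c_to_p	0.4	0
0-20	Overall	c_to_p	0.7	0.3
0-20	CK	n_to_p	0.6	0
0-20	Y5	n_to_p	0.5	0
0-20	Y10	n_to_p	0.5	0
0-20	Y15	n_to_p	0.3	0
0-20	Overall	n_to_p	0.5	0.1
20-40	CK	BG	207.6	11.9
20-40	Y5	BG	114.2	5.6
20-40	Y10	BG	120.9	9.9
20-40	Y15	BG	91.6	2.7
20-40	Overall	BG	133.5	50.9
20-40	CK	CBH	26.3	3
20-40	Y5	CBH	17.4	2.3
20-40	Y10	CBH	12	0.9
20-40	Y15	CBH	10.4	0.8
20-40	Overall	CBH	16.5	7.2
20-40	CK	NAG	28.1	1.6
20-40	Y5	NAG	16.7	2.4
20-40	Y10	NAG	13.6	2
20-40	Y15	NAG	20.5	1.4
20-40	Overall	NAG	19.7	6.3
20-40	CK	LAP	112.1	5.5
20-40	Y5	LAP	82.3	5
20-40	Y10	LAP	114.8	2.8
20-40	Y15	LAP	105.5	2.5
20-40	Overall	LAP	103.7	14.8
20-40	CK	ALP	327.7	15.1
20-40	Y5	ALP	274.4	9.2
20-40	Y10	ALP	288.3	15.2
20-40	Y15	ALP	305.9	12.9
20-40	Overall	ALP	299.1	23
20-40	CK	c_to_n	1.7	0.1
20-40	Y5	c_to_n	1.3	0.1
20-40	Y10	c_to_n	1	0.1
20-40	Y15	c_to_n	0.8	0
20-40	Overall	c_to_n	1.2	0.4
20-40	CK	c_to_p	0.7	0.1
20-40	Y5	c_to_p	0.5	0
20-40	Y10	c_to_p	0.5	0.1
20-40	Y15	c_to_p	0.3	0
20-40	Overall	c_to_p	0.5	0.2
20-40	CK	n_to_p	0.4	0
20-40	Y5	n_to_p	0.4	0
20-40	Y10	n_to_p	0.4	0
20-40	Y15	n_to_p	0.4	0
20-40	Overall	n_to_p	0.4	0
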
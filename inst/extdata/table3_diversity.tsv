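depth	treatment	variable	mean	sd
0-20	CK	bacterial_chao1	4576	607.8
0-20	Y5	bacterial_chao1	4803.6	656.6
0-20	Y10	bacterial_chao1	5209.3	21.3
0-20	Y15	bacterial_chao1	4780.9	357.5
0-20	Overall	bacterial_chao1	4842.5	506.9
0-20	CK	bacterial_shannon	9.5	0.4
0-20	Y5	bacterial_shannon	9.8	0.5
0-20	Y10	bacterial_shannon	10.1	0.1
0-20	Y15	bacterial_shannon	9.8	0.5
0-20	Overall	bacterial_shannon	9.8	0.4
0-20	CK	bacterial_simpson	1	0
0-20	Y5	bacterial_simpson	1	0
0-20	Y10	bacterial_simpson	1	0
0-20	Y15	bacterial_simpson	1	0
0-20	Overall	bacterial_simpson	1	0
0-20	CK	fungal_chao1	499.9	164.9
0-20	Y5	fungal_chao1	527.5	183.2
0-20	Y10	fungal_chao1	647	97.4
0-20	Y15	fungal_chao1	533.7	82.1
0-20	Overall	fungal_chao1	552	141.6
0-20	CK	fungal_shannon	5.8	1.6
0-20	Y5	fungal_shannon	5.8	0.6
0-20	Y10	fungal_shannon	5.1	0.7
0-20	Y15	fungal_shannon	5	0.4
0-20	Overall	fungal_shannon	5.4	0.9
0-20	CK	fungal_simpson	0.9	0.2
0-20	Y5	fungal_simpson	0.9	0
0-20	Y10	fungal_simpson	0.9	0.1
0-20	Y15	fungal_simpson	0.9	0.1
0-20	Overall	fungal_simpson	0.9	0.1
20-40	CK	bacterial_chao1	4775.4	325.6
20-40	Y5	bacterial_chao1	4316.8	477.6
20-40	Y10	bacterial_chao1	5036.5	302.4
20-40	Y15	bacterial_chao1	4757.3	366.7
20-40	Overall	bacterial_chao1	4721.5	437.5
20-40	CK	bacterial_shannon	9.7	0.2
20-40	Y5	bacterial_shannon	9.4	0.3
20-40	Y10	bacterial_shannon	10	0.3
20-40	Y15	bacterial_shannon	9.8	0.4
20-40	Overall	bacterial_shannon	9.7	0.4
20-40	CK	bacterial_simpson	1	0
20-40	Y5	bacterial_simpson	1	0
20-40	Y10	bacterial_simpson	1	0
20-40	Y15	bacterial_simpson	1	0
20-40	Overall	bacterial_simpson	1	0
20-40	CK	fungal_chao1	564.7	69.6
20-40	Y5	fungal_chao1	363.1	83.2
20-40	Y10	fungal_chao1	478.8	190.9
20-40	Y15	fungal_chao1	505.4	120.3
20-40	Overall	fungal_chao1	478	138.7
20-40	CK	fungal_shannon	5.9	1.3
20-40	Y5	fungal_shannon	5.7	0.4
20-40	Y10	fungal_shannon	4.9	0.8
20-40	Y15	fungal_shannon	5.3	0.6
20-40	Overall	fungal_shannon	5.4	0.9
20-40	CK	fungal_simpson	0.9	0.1
20-40	Y5	fungal_simpson	1	0
20-40	Y10	fungal_simpson	0.9	0.1
20-40	Y15	fungal_simpson	0.9	0.1
20-40	Overall	fungal_simpson	0.9	0.1
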
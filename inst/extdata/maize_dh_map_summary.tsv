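population	parent1	parent2	cross_type	n_lines	length_cm	gwrr
CFD01	F353	UH007	DxF	86	1536.6	0.748
CFD02	F353	B73	DxD	73	1319.6	0.642
CFD03	F353	D06	DxD	103	1347.3	0.656
CFD04	F353	D09	DxD	105	1432.9	0.697
CFD05	F353	EC169	DxD	77	1179.7	0.574
CFD06	F353	F252	DxD	105	1441.2	0.701
CFD07	F353	F618	DxD	108	1334.5	0.649
CFD09	F353	Mo17	DxD	63	1287.4	0.627
CFD10	F353	UH250	DxD	99	1288.7	0.627
CFD11	F353	UH304	DxD	86	1537.7	0.748
CFD12	F353	W117	DxD	100	1360.8	0.662
CFF01	UH007	F353	FxD	99	1507.0	0.733
CFF02	UH007	B73	FxD	120	1666.6	0.811
CFF03	UH007	D152	FxF	112	1893.1	0.921
CFF04	UH007	EC49A	FxF	53	1535.6	0.747
CFF06	UH007	EZ5	FxF	50	1785.0	0.869
CFF07	UH007	F03802	FxF	129	1630.3	0.793
CFF08	UH007	F2	FxF	77	1554.9	0.757
CFF09	UH007	F283	FxF	134	1442.1	0.702
CFF10	UH007	F64	FxF	108	1437.3	0.699
CFF12	UH007	UH006	FxF	114	1654.6	0.805
CFF13	UH007	UH009	FxF	117	1768.6	0.861
CFF15	UH007	DK105	FxF	115	1751.6	0.852
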
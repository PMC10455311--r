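# Published selected feature subset for the folding-rate-change regression
# predictor (21 features), with the reported weighted-importance scores.
rank	feature	score
1	rsa	36.000
2	C-score	29.361
3	rp	26.525
4	ZHAC000105	21.893
5	MOOG990101	18.082
6	ZHAC000102	16.647
7	BASU010101	16.462
8	window_T	15.404
9	SIMK990105	15.355
10	window_PolarAA	15.248
11	KESO980102	14.054
12	SIMK990102	12.777
13	window_G	11.407
14	window_Y	9.909
15	window_F	9.617
16	window_PosAA	9.447
17	window_V	8.810
18	window_D	7.500
19	SNEP660101	1.844
20	BULH740101	1.159
21	LAWE840101	1.155
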
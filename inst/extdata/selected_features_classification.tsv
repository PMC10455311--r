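# Published selected feature subset for the three-class folding-rate
# classifier (31 features), with the reported weighted-importance scores.
rank	feature	score
1	C-score	55.23
2	rp	36.11
3	rsa	34.95
4	TOBD000102	30.58
5	SIMK990102	26.75
6	THOP960101	24.22
7	VENM980101	23.08
8	BONM030106	17.72
9	window_Y	16.35
10	MOOG990101	15.31
11	BONM030105	14.42
12	window_NonPolarAA	10.77
13	BETM990101	10.65
14	MIYS850103	8.38
15	window_ChargedAA	8.35
16	window_PosAA	8.10
17	BONM030101	7.63
18	window_F	7.62
19	SKOJ970101	7.01
20	window_R	4.77
21	window_D	4.22
22	AURR980118	2.90
23	LIWA970101	2.85
24	GARJ730101	1.43
25	BULH740101	1.38
26	OVEJ920103	0.98
27	QIAN880128	0.98
28	AURR980102	0.99
29	NADH010101	0.18
30	g2_g6	0.001
31	V_A	0.001
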
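batch	panel	RSD_pct	n	MQS_kg
PG01	six_peaks	9.85	113.07	0.113
PG02	six_peaks	28.10	920.99	0.921
PG03	six_peaks	36.31	1537.46	1.537
PG04	six_peaks	5.66	37.37	0.037
PG05	six_peaks	17.66	363.74	0.364
GG	six_peaks	8.97	93.85	0.094
FG	six_peaks	51.30	3070.03	3.070
PG01	three_ginsenosides	8.54	85.13	0.085
PG02	three_ginsenosides	20.62	495.83	0.496
PG03	three_ginsenosides	42.41	2097.62	2.098
PG04	three_ginsenosides	5.79	39.15	0.039
PG05	three_ginsenosides	15.08	265.30	0.265
GG	three_ginsenosides	7.06	58.17	0.058
FG	three_ginsenosides	51.54	3098.48	3.098
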
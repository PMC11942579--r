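batch	RSD_pct	n	MQS_kg
PG01	6.16	44.30	0.044
PG02	6.07	43.02	0.043
PG03	10.99	141.00	0.141
PG04	4.52	23.86	0.024
PG05	9.25	99.80	0.998
GG	5.75	38.53	0.039
FG	9.83	112.79	0.113
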
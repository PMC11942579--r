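batch	sample	tnb	H_published
PG01	PG01-1	70	0.3943
PG01	PG01-2	72	0.3536
PG01	PG01-3	70	0.3943
PG02	PG02-1	33	1.4792
PG02	PG02-2	37	1.3141
PG02	PG02-3	34	1.4361
PG03	PG03-1	47	0.9690
PG03	PG03-2	41	1.1660
PG03	PG03-3	47	0.9690
PG04	PG04-1	37	1.3141
PG04	PG04-2	40	1.2016
PG04	PG04-3	38	1.2756
PG05	PG05-1	36	1.3536
PG05	PG05-2	42	1.1312
PG05	PG05-3	40	1.2016
GG	GG1	81	0.1837
GG	GG2	82	0.1660
GG	GG3	81	0.1837
FG	FG1	50	0.8797
FG	FG2	47	0.9690
FG	FG3	53	0.7956
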